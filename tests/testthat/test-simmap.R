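# Forward simulation, endpoint-conditioned stochastic maps, summaries.

test_that("forward simulation respects degenerate generators", {
  sp <- karyo_states(6, 12)
  tr <- yule_tree(6, seed = 2)
  # all rates zero: one segment per branch, no events
  m0 <- sim_karyo_history(tr, karyo_rate_matrix(sp, karyo_rates()), sp,
                          seed = 1)
  validate_karyo_map(m0)
  expect_equal(nrow(map_events(m0)), 0)
  expect_true(all(vapply(m0$edge_maps, function(s) length(s$states), 1L) == 1))
  s0 <- summarize_map(m0)
  expect_equal(unname(s0$time_in_state["12_XY"]), 1)
  expect_equal(sum(s0$counts), 0)
  # rho-only generator from an XY root: XY states are absorbing
  mr <- sim_karyo_history(tr, karyo_rate_matrix(sp, karyo_rates(rho = 5)), sp,
                          seed = 2)
  expect_equal(nrow(map_events(mr)), 0)
  # determinism under the seed
  m1 <- sim_karyo_history(tr, karyo_rate_matrix(sp, karyo_rates(1, 1, 1, 1)),
                          sp, seed = 9)
  m2 <- sim_karyo_history(tr, karyo_rate_matrix(sp, karyo_rates(1, 1, 1, 1)),
                          sp, seed = 9)
  expect_identical(m1$edge_maps, m2$edge_maps)
})

test_that("low-rate forward simulation thins like a Poisson process", {
  # away from the boundaries, total event rate is delta+gamma+sigma = 0.03,
  # so the mean event count over the tree is ~0.03 x total length
  sp <- karyo_states(6, 40)
  Q <- karyo_rate_matrix(sp, karyo_rates(0.01, 0.01, 0.01, 0))
  tr <- yule_tree(8, seed = 4, scale_depth = 1)
  L <- sum(tr$edge.length)
  set.seed(31)
  counts <- vapply(1:2000, function(i) {
    m <- sim_karyo_history(tr, Q, sp, root_state = list(i = 20L, system = "XY"))
    sum(summarize_map(m)$counts)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 0.03 * L), 4 * stats::sd(counts) / sqrt(2000))
})

test_that("conditional maps reproduce tips and degenerate cases", {
  sp <- karyo_states(6, 12)
  tr <- yule_tree(5, seed = 3)
  tips <- data.frame(taxon = tr$tip.label, diploid_number = 12L, system = "XY")
  maps <- karyo_simmap(tr, tips, karyo_rate_matrix(sp, karyo_rates()), sp,
                       n_maps = 5, seed = 1)
  for (m in maps) {
    validate_karyo_map(m)
    expect_equal(nrow(map_events(m)), 0)
  }
  # maps always hit the observed tip states
  Q <- karyo_rate_matrix(sp, karyo_rates(0.6, 0.5, 0.5, 0.8))
  sim <- synthesize(n_tips = 12, rates = karyo_rates(0.6, 0.5, 0.5, 0.8),
                    seed = 8)
  maps <- karyo_simmap(sim$tree, sim$tip_states, Q, sp, n_maps = 25, seed = 2)
  idx <- tip_indices(sim$tip_states, sp)
  for (m in maps) {
    validate_karyo_map(m)
    expect_equal(unname(m$node_states[seq_len(12)]),
                 unname(idx[sim$tree$tip.label]))
  }
  # determinism
  mapsA <- karyo_simmap(sim$tree, sim$tip_states, Q, sp, n_maps = 3, seed = 7)
  mapsB <- karyo_simmap(sim$tree, sim$tip_states, Q, sp, n_maps = 3, seed = 7)
  expect_identical(lapply(mapsA, `[[`, "edge_maps"),
                   lapply(mapsB, `[[`, "edge_maps"))
  # impossible data are refused
  expect_error(
    karyo_simmap(tr, tips, karyo_rate_matrix(sp, karyo_rates()), sp,
                 root = list(type = "fixed", i = 10L, system = "XY"),
                 n_maps = 2, seed = 1),
    "zero likelihood")
})

test_that("endpoint-conditioned jump law matches the scalar closed form", {
  # two-state rho-only subsystem: from neoXY, decay to XY at rate rho; an
  # edge conditioned neoXY -> XY carries exactly one jump whose time has
  # density rho e^(-rho u) / (1 - e^(-rho t)) on (0, t); an edge
  # conditioned neoXY -> neoXY carries none.
  sp <- karyo_states(6, 6)
  rho <- 0.9
  Q <- karyo_rate_matrix(sp, karyo_rates(rho = rho))
  tr <- read_newick("(A:1,B:1);", text = TRUE)
  tips <- data.frame(taxon = c("A", "B"), diploid_number = 6L,
                     system = c("XY", "neoXY"))
  maps <- karyo_simmap(tr, tips, Q, sp,
                       root = list(type = "fixed", i = 6L, system = "neoXY"),
                       n_maps = 2000, seed = 12)
  eA <- which(tr$edge[, 2] == which(tr$tip.label == "A"))
  eB <- which(tr$edge[, 2] == which(tr$tip.label == "B"))
  njumpA <- vapply(maps, function(m) length(m$edge_maps[[eA]]$states) - 1L, 1L)
  njumpB <- vapply(maps, function(m) length(m$edge_maps[[eB]]$states) - 1L, 1L)
  expect_true(all(njumpA == 1L))
  expect_true(all(njumpB == 0L))
  jt <- vapply(maps, function(m) m$edge_maps[[eA]]$durations[1], numeric(1))
  ks <- stats::ks.test(jt, function(u) (1 - exp(-rho * u)) / (1 - exp(-rho)))
  expect_gt(ks$p.value, 0.01)
})

test_that("map summaries do plain arithmetic and add over branches", {
  sp <- karyo_states(6, 12)
  tr <- read_newick("(A:2,B:1);", text = TRUE)
  # hand-built map: one SA-fusion at the midpoint of the branch to A
  i12 <- match("12_XY", rownames(sp)); i10n <- match("10_neoXY", rownames(sp))
  map <- karyofuse:::new_karyo_map(
    tr, sp,
    list(list(states = c(i12, i10n), durations = c(1, 1)),
         list(states = i12, durations = 1)),
    c(A = i10n, B = i12, root = i12)[c(1, 2, 3)])
  validate_karyo_map(map)
  s <- summarize_map(map)
  expect_equal(unname(s$time_in_state[c("12_XY", "10_neoXY")]), c(2 / 3, 1 / 3))
  expect_equal(unname(s$counts["SA_fusion"]), 1L, ignore_attr = TRUE)
  expect_equal(sum(s$counts), 1)
  ev <- map_events(map)
  expect_equal(ev$class, "SA_fusion")
  expect_equal(ev$time, 1)
  # additivity: occupancy equals the length-weighted mean of per-branch maps
  occ_branch <- vapply(seq_len(2), function(e) {
    seg <- map$edge_maps[[e]]
    sum(seg$durations[seg$states == i12]) / sum(seg$durations)
  }, numeric(1))
  w <- tr$edge.length / sum(tr$edge.length)
  expect_equal(unname(s$time_in_state["12_XY"]), sum(w * occ_branch))
  # corrupted maps are caught
  bad <- map; bad$edge_maps[[1]]$durations <- c(1, 1.5)
  expect_error(validate_karyo_map(bad), "durations")
  bad2 <- map; bad2$edge_maps[[1]]$states <- c(i12, match("6_XY", rownames(sp)))
  expect_error(validate_karyo_map(bad2), "forbidden|child state")
})

test_that("node frequencies across maps match posterior marginals", {
  fx <- fixture_4tip()
  post <- node_marginals(fx$tree, fx$tips, fx$Q, fx$space, fx$root)
  # marginals themselves agree with exhaustive enumeration
  pr <- karyofuse:::root_prior(fx$root, fx$space)
  idx <- tip_indices(fx$tips, fx$space)
  for (v in 5:7)
    expect_equal(unname(post[v, ]),
                 oracle_node_marginal(fx$tree, idx, fx$Q, pr, v),
                 tolerance = 1e-9)
  maps <- karyo_simmap(fx$tree, fx$tips, fx$Q, fx$space, fx$root,
                       n_maps = 1500, seed = 4)
  freq <- matrix(0, 7, 8)
  for (m in maps)
    freq[cbind(1:7, m$node_states)] <- freq[cbind(1:7, m$node_states)] + 1
  freq <- freq / length(maps)
  for (v in 5:7) for (s in 1:8) {
    se <- sqrt(max(post[v, s] * (1 - post[v, s]), 1e-6) / length(maps))
    expect_lt(abs(freq[v, s] - post[v, s]), 4 * se + 1e-9)
  }
})

test_that("maps round-trip through the annotated-Newick and JSON forms", {
  sim <- synthesize(n_tips = 8, rates = karyo_rates(0.6, 0.5, 0.5, 0.8),
                    seed = 21)
  map <- sim$true_history
  # node/edge numbering may legitimately change on re-read, so compare
  # numbering-invariant content: per-tip terminal states (by label),
  # occupancy by state label, event tallies, and per-branch durations
  # matched through the tip-to-root path structure.
  invariants <- function(m) {
    s <- summarize_map(m)
    tipst <- rownames(m$space)[m$node_states[seq_along(m$tree$tip.label)]]
    list(tips = stats::setNames(tipst, m$tree$tip.label),
         occ = s$time_in_state, counts = s$counts,
         total = s$total_length,
         n_segments = sum(vapply(m$edge_maps, function(e)
           length(e$states), 1L)))
  }
  ref <- invariants(map)
  txt <- withr::local_tempfile(fileext = ".simmap")
  write_karyo_map(map, txt, format = "simmap")
  back <- read_karyo_map(txt, format = "simmap")
  validate_karyo_map(back)
  got <- invariants(back)
  expect_identical(got$tips[names(ref$tips)], ref$tips)
  expect_equal(got$occ[names(got$occ)],
               ref$occ[names(got$occ)], tolerance = 1e-12)
  expect_identical(unname(got$counts), unname(ref$counts))
  expect_equal(got$total, ref$total, tolerance = 1e-12)
  expect_identical(got$n_segments, ref$n_segments)
  # writing the re-read map reproduces the same set of annotations
  expect_setequal(
    strsplit(gsub("[();]", ",", format_karyo_map(back)), ",")[[1]],
    strsplit(gsub("[();]", ",", readLines(txt)), ",")[[1]])
  js <- withr::local_tempfile(fileext = ".json")
  write_karyo_map(map, js, format = "json")
  backj <- read_karyo_map(js, format = "json")
  validate_karyo_map(backj)
  gotj <- invariants(backj)
  expect_identical(gotj$tips[names(ref$tips)], ref$tips)
  # branch lengths in the embedded Newick limit agreement to ~1e-10
  expect_equal(gotj$occ, ref$occ[names(gotj$occ)], tolerance = 1e-8)
  expect_identical(unname(gotj$counts), unname(ref$counts))
  expect_identical(gotj$n_segments, ref$n_segments)
})
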