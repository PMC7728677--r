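#' Karyotype descriptions for the fusion null model
#'
#' A karyotype is described by its diploid autosome count and the sex
#' chromosome complement of the heterogametic sex. The same closed-form
#' machinery serves three families of sex chromosome systems:
#'
#' * `"XY"` (male heterogamety, including XO and multi-X variants): `x` is
#'   the number of X chromosomes in males, `y` the number of Y chromosomes
#'   in males.
#' * `"ZW"` (female heterogamety): by symmetry the sexes are exchanged, so
#'   `x` holds the Z count in females and `y` the W count; the sex-bias
#'   parameter is then the proportion of fusions occurring in males (the
#'   homogametic sex).
#' * `"UV"` (haploid-phase systems with equal U and V counts): both sex
#'   chromosome slots carry the V count and the sex-bias term is fixed at
#'   zero because there is no homogametic diploid sex.
#'
#' Derived quantities are the heterogametic-sex diploid number
#' `Ds = Da + x + y` and the homogametic-sex diploid number `Dd = Da + 2x`
#' (two copies of each X/Z in the homogametic sex).
#'
#' @param autosomes diploid autosome count `Da`; must be an even
#'   non-negative integer (autosomes come in homologous pairs).
#' @param x X count in males (XY-like), Z count in females (ZW-like), or V
#'   count (UV).
#' @param y Y count in males (XY-like) or W count in females (ZW-like);
#'   ignored for UV (forced equal to `x`).
#' @param system one of `"XY"`, `"ZW"`, `"UV"`.
#' @return an object of class `"karyotype"` with fields `Da`, `Xs`, `Y`,
#'   `system`, `Ds`, `Dd`.
#' @examples
#' karyotype(26, x = 2, y = 0)           # X1X2O, e.g. Habronattus
#' karyotype(14)                         # plain XY
#' karyotype(14, x = 1, y = 1, system = "ZW")
#' @export
karyotype <- function(autosomes, x = 1L, y = 1L, system = c("XY", "ZW", "UV")) {
  system <- match.arg(system)
  for (nm in c("autosomes", "x", "y")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        v != round(v))
      stop(sprintf("'%s' must be a single non-negative integer", nm))
  }
  autosomes <- as.integer(autosomes)
  x <- as.integer(x)
  y <- as.integer(y)
  if (autosomes %% 2L != 0L)
    stop("diploid autosome count 'autosomes' (Da) must be even: autosomes come in homologous pairs")
  if (system == "UV" && y != x)
    stop("UV systems require equal U and V counts; unequal counts are not supported")
  structure(
    list(Da = autosomes, Xs = x, Y = y, system = system,
         Ds = autosomes + x + y, Dd = autosomes + 2L * x),
    class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  lab <- switch(x$system,
    XY = sprintf("%s%s", strrep("X", max(x$Xs, 0)),
                 if (x$Y > 0) strrep("Y", x$Y) else "O"),
    ZW = sprintf("%s%s", strrep("Z", max(x$Xs, 0)),
                 if (x$Y > 0) strrep("W", x$Y) else "O"),
    UV = sprintf("U%sV%s", x$Xs, x$Y))
  cat(sprintf("Karyotype: %s system (%s), Da = %d, Ds = %d, Dd = %d\n",
              x$system, lab, x$Da, x$Ds, x$Dd))
  invisible(x)
}

## Shared preconditions for the closed-form probabilities. `mu` is the
## proportion of fusions arising in the homogametic sex; its diploid number
## Dd only enters the formulas when mu > 0.
check_karyotype_eval <- function(k, mu) {
  if (!inherits(k, "karyotype"))
    k <- do.call(karyotype, k)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0 || mu > 1)
    stop("sex-bias 'mu' must be a single probability in [0, 1]")
  if (k$system == "UV" && mu != 0)
    stop("UV systems have no homogametic diploid sex; 'mu' must be 0")
  if (k$Ds <= 2L)
    stop(sprintf("heterogametic diploid number Ds = %d must exceed 2 (denominator Ds(Ds-2))", k$Ds))
  if (mu > 0 && k$Dd <= 2L)
    stop(sprintf("homogametic diploid number Dd = %d must exceed 2 (denominator Dd(Dd-2))", k$Dd))
  k
}

## Absorb floating-point excursions at the rounding level only; anything
## larger indicates an internal inconsistency and is raised, not masked.
clamp_prob <- function(p, what) {
  tol <- 64 * .Machine$double.eps
  if (any(p < -tol) || any(p > 1 + tol))
    stop(sprintf("internal inconsistency: %s = %.17g outside [0, 1]", what, p))
  pmin(pmax(p, 0), 1)
}

#' Null probability that a fusion joins two sex chromosomes
#'
#' Under the null model that any chromosome is equally likely to fuse with
#' any non-homologous chromosome, the probability that a random fusion is an
#' SS-fusion is a mixture over the sex in which the fusion arises:
#' \deqn{P(SS) = \mu \frac{4 X_s (X_s - 1)}{D_d (D_d - 2)} + (1-\mu)\left[
#'   \frac{X_s (X_s - 1)}{D_s (D_s + X_s - 1)} +
#'   \frac{Y (Y - 1)}{D_s (D_s + Y - 1)}\right].}
#' Both terms vanish in systems with a single X and a single Y.
#'
#' @param k a [karyotype()].
#' @param mu proportion of fusions originating in the homogametic sex
#'   (females for XY-like systems, males for ZW-like); in `[0, 1]`.
#' @return a probability.
#' @export
p_ss <- function(k, mu = 0.5) {
  k <- check_karyotype_eval(k, mu)
  Xs <- k$Xs; Y <- k$Y; Ds <- k$Ds; Dd <- k$Dd
  hom <- if (mu > 0) 4 * Xs * (Xs - 1) / (Dd * (Dd - 2)) else 0
  het <- Xs * (Xs - 1) / (Ds * (Ds + Xs - 1)) +
         Y  * (Y  - 1) / (Ds * (Ds + Y  - 1))
  clamp_prob(mu * hom + (1 - mu) * het, "P(SS)")
}

#' Null probability that a fusion joins two autosomes
#'
#' \deqn{P(AA) = \mu \frac{D_a (D_a - 2)}{D_d (D_d - 2)} +
#'   (1-\mu) \frac{D_a (D_a - 2)}{D_s (D_s - 2)},}
#' the probability that both members of a uniformly chosen non-homologous
#' chromosome pair are autosomes, averaged over the sex of origin.
#'
#' @inheritParams p_ss
#' @return a probability.
#' @export
p_aa <- function(k, mu = 0.5) {
  k <- check_karyotype_eval(k, mu)
  Da <- k$Da; Ds <- k$Ds; Dd <- k$Dd
  num <- Da * (Da - 2)
  hom <- if (mu > 0) num / (Dd * (Dd - 2)) else 0
  clamp_prob(mu * hom + (1 - mu) * num / (Ds * (Ds - 2)), "P(AA)")
}

#' Null probability that a fusion joins a sex chromosome and an autosome
#'
#' The complement of the other two fusion classes,
#' \eqn{P(SA) = 1 - P(AA) - P(SS)}. For a plain XY (or ZW) system with one
#' X and one Y this reduces to the closed form \eqn{4 / (D_a + 2)}.
#'
#' @inheritParams p_ss
#' @return a probability.
#' @examples
#' p_sa(karyotype(14))                   # 0.25
#' p_sa(karyotype(26, x = 2, y = 0), mu = 0)
#' @export
p_sa <- function(k, mu = 0.5) {
  clamp_prob(1 - p_aa(k, mu) - p_ss(k, mu), "P(SA)")
}

#' All three fusion-class probabilities at once
#'
#' Bundles [p_sa()], [p_aa()] and [p_ss()]; the three components sum to one
#' by construction (the SA component is computed as the complement).
#'
#' @inheritParams p_ss
#' @return an object of class `"fusion_probs"`: a named numeric vector
#'   `c(p_sa, p_aa, p_ss)` with the karyotype and `mu` attached as
#'   attributes.
#' @examples
#' fusion_probabilities(karyotype(26, x = 2, y = 0), mu = 0.5)
#' @export
fusion_probabilities <- function(k, mu = 0.5) {
  if (!inherits(k, "karyotype")) k <- do.call(karyotype, k)
  if (k$system == "UV" && missing(mu)) mu <- 0
  aa <- p_aa(k, mu); ss <- p_ss(k, mu)
  structure(c(p_sa = clamp_prob(1 - aa - ss, "P(SA)"), p_aa = aa, p_ss = ss),
            karyotype = k, mu = mu, class = "fusion_probs")
}

#' @export
print.fusion_probs <- function(x, digits = 6, ...) {
  k <- attr(x, "karyotype")
  cat(sprintf("Fusion-class null probabilities (%s, Da = %d, mu = %g)\n",
              k$system, k$Da, attr(x, "mu")))
  print(round(c(unclass(x)), digits))
  invisible(x)
}

#' Fusion probabilities for a UV sex chromosome system
#'
#' UV systems (e.g. bryophytes) have no homogametic diploid sex, so the
#' sex-bias term is fixed at zero and both sex chromosome slots carry the V
#' count. Only equal U and V counts are supported.
#'
#' @param autosomes diploid autosome count (even).
#' @param v number of V (equivalently U) chromosomes.
#' @return a `"fusion_probs"` vector.
#' @export
fusion_probabilities_uv <- function(autosomes, v = 1L) {
  fusion_probabilities(karyotype(autosomes, x = v, y = v, system = "UV"), mu = 0)
}

## Named sex chromosome system templates used by sa_sweep() and the CLI.
system_template <- function(name) {
  switch(name,
    XY  = list(x = 1L, y = 1L, system = "XY"),
    XO  = list(x = 1L, y = 0L, system = "XY"),
    XXY = list(x = 2L, y = 1L, system = "XY"),
    XXO = list(x = 2L, y = 0L, system = "XY"),
    ZW  = list(x = 1L, y = 1L, system = "ZW"),
    ZO  = list(x = 1L, y = 0L, system = "ZW"),
    UV  = list(x = 1L, y = 1L, system = "UV"),
    stop(sprintf("unknown sex chromosome system template '%s'", name)))
}

#' Sweep the SA-fusion probability over diploid autosome counts
#'
#' Evaluates `p_sa` on a grid of diploid autosome counts for one or more
#' sex chromosome systems, reproducing the familiar decay of the expected
#' SA-fusion proportion as autosome number grows.
#'
#' @param systems character vector of system templates among `"XY"`,
#'   `"XO"`, `"XXY"`, `"XXO"`, `"ZW"`, `"ZO"`, `"UV"`.
#' @param da even diploid autosome counts to evaluate.
#' @param mu sex-bias parameter passed to [p_sa()] (forced to 0 for UV).
#' @return a data frame of class `"sa_sweep"` with columns `system`, `Da`,
#'   `p_sa`, ordered by system then `Da`.
#' @examples
#' sa_sweep("XY", da = seq(6, 16, by = 2))
#' @export
sa_sweep <- function(systems = c("XY", "XO", "XXY", "XXO"),
                     da = seq(6L, 30L, by = 2L), mu = 0.5) {
  if (length(da) == 0L || length(systems) == 0L) {
    out <- data.frame(system = character(), Da = integer(), p_sa = numeric())
    class(out) <- c("sa_sweep", "data.frame")
    return(out)
  }
  rows <- lapply(systems, function(sys) {
    tpl <- system_template(sys)
    m <- if (tpl$system == "UV") 0 else mu
    data.frame(system = sys, Da = as.integer(da),
               p_sa = vapply(da, function(a)
                 p_sa(karyotype(a, tpl$x, tpl$y, tpl$system), m), numeric(1)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sa_sweep", "data.frame")
  attr(out, "mu") <- mu
  out
}

#' @export
plot.sa_sweep <- function(x, ...) {
  syss <- unique(x$system)
  cols <- seq_along(syss)
  plot(NULL, xlim = range(x$Da), ylim = c(0, max(x$p_sa)),
       xlab = "Diploid autosome count", ylab = "Proportion SA-fusions", ...)
  for (i in seq_along(syss)) {
    d <- x[x$system == syss[i], ]
    lines(d$Da, d$p_sa, col = cols[i], lwd = 2)
    points(d$Da, d$p_sa, col = cols[i], pch = 16)
  }
  abline(h = 0.25, lty = 3)
  legend("topright", legend = syss, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Append fusion probabilities to a karyotype table
#'
#' Batch interface: takes a data frame with columns `label`, `Da`, `Xs`,
#' `Y`, `system` and optionally `mu_d`, and appends columns `p_sa`, `p_aa`,
#' `p_ss`.
#'
#' @param tab data frame of karyotypes, one row per taxon or population.
#' @param mu default sex-bias used where the table has no `mu_d` column.
#' @return the input with three probability columns appended.
#' @export
fusion_prob_table <- function(tab, mu = 0.5) {
  need <- c("label", "Da", "Xs", "Y", "system")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("karyotype table lacks column(s): %s", paste(miss, collapse = ", ")))
  mus <- if ("mu_d" %in% names(tab)) tab$mu_d else rep(mu, nrow(tab))
  pr <- t(vapply(seq_len(nrow(tab)), function(i) {
    k <- karyotype(tab$Da[i], tab$Xs[i], tab$Y[i], tab$system[i])
    unclass(fusion_probabilities(k, if (k$system == "UV") 0 else mus[i]))
  }, numeric(3)))
  cbind(tab, as.data.frame(pr))
}
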