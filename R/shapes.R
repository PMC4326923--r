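#' Quadratic trajectory fits for U/bell classification
#'
#' Fits `value = a * age^2 + b * age + c` by ordinary least squares to each
#' gene's per-sample normalized expression (all samples, one point per
#' sample, preserving `n - 3` residual degrees of freedom), tests the
#' quadratic coefficient with a two-sided t-test, and classifies genes with
#' `p_quad < alpha` as `u` (upward curvature, trough) or `bell` (downward
#' curvature, peak). The trajectory vertex `-b / (2a)` estimates the
#' inversion age; vertices outside the sampled age range are retained but
#' flagged. No multiplicity correction is applied across genes: the
#' classification criterion is a per-gene `P < 0.05`.
#'
#' @param ae an [AgingExperiment-class].
#' @param genes gene ids to fit (default all).
#' @param assay assay to fit on, normally `"logrpkm"`.
#' @param alpha significance level for shape assignment.
#' @return data.frame with columns `gene`, `a`, `b`, `c`, `p_quad`,
#'   `vertex_age`, `shape` (`"u"`, `"bell"` or `"none"`), `in_range`.
#' @export
fitShapes <- function(ae, genes = rownames(ae), assay = "logrpkm",
                      alpha = 0.05) {
  x <- assayMatrix(ae, assay)
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("genes absent from the experiment: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  Y <- t(x[genes, , drop = FALSE])            # samples x genes
  age <- unname(ageWeeks(ae))
  fit <- quadraticFit(Y, age)
  fit$gene <- genes
  fit$shape <- ifelse(fit$p_quad < alpha & fit$a != 0,
                      ifelse(fit$a > 0, "u", "bell"), "none")
  fit$in_range <- !is.na(fit$vertex_age) &
    fit$vertex_age >= min(age) & fit$vertex_age <= max(age)
  fit[c("gene", "a", "b", "c", "p_quad", "vertex_age", "shape", "in_range")]
}

#' Closed-form quadratic OLS over many response vectors
#'
#' Solves the normal equations of the quadratic regression once for the
#' shared design and applies them to every response column. The p-value is
#' a two-sided t-test of the quadratic coefficient with `n - 3` residual
#' degrees of freedom.
#'
#' @param Y numeric matrix of responses, samples x genes (a vector is
#'   treated as one gene).
#' @param age numeric vector of per-sample ages; at least 3 distinct
#'   values and 6 samples are required.
#' @return data.frame with columns `a`, `b`, `c`, `se_a`, `p_quad`,
#'   `vertex_age`.
#' @export
quadraticFit <- function(Y, age) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  n <- nrow(Y)
  if (length(age) != n) stop("length(age) must match nrow(Y)")
  if (length(unique(age)) < 3L)
    stop("quadratic fit needs at least 3 distinct ages")
  if (n < 6L) stop("quadratic fit needs at least 6 samples")
  # center age for numerical stability, then map coefficients back
  ac <- age - mean(age)
  X <- cbind(1, ac, ac^2)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, Y))          # 3 x genes, centered basis
  resid <- Y - X %*% beta
  df <- n - 3L
  sigma2 <- colSums(resid^2) / df
  covA <- solve(XtX)[3L, 3L]
  seA <- sqrt(sigma2 * covA)
  tA <- beta[3L, ] / seA
  p <- 2 * stats::pt(-abs(tA), df = df)
  # numerically perfect fits: significance is decided by whether the
  # quadratic coefficient is nonzero at the response's scale
  scale <- colMeans(Y^2) + 1e-300
  degen <- sigma2 <= scale * 1e-20
  if (any(degen))
    p[degen] <- ifelse(abs(beta[3L, degen]) > sqrt(scale[degen]) * 1e-10,
                       0, 1)
  # back-transform: y = a*(t - mbar)^2 + b2*(t - mbar) + b1
  mbar <- mean(age)
  a <- beta[3L, ]
  b <- beta[2L, ] - 2 * beta[3L, ] * mbar
  cc <- beta[1L, ] - beta[2L, ] * mbar + beta[3L, ] * mbar^2
  vertex <- ifelse(a != 0, -b / (2 * a), NA_real_)
  data.frame(a = a, b = b, c = cc, se_a = seA, p_quad = pmin(pmax(p, 0), 1),
             vertex_age = vertex, row.names = NULL)
}

#' Summarize the distribution of trajectory inversion ages
#'
#' Counts U- and bell-classified genes, reports the median vertex (peak or
#' trough) age per shape, and bins in-range vertices into fixed-width
#' histograms spanning the sampled age range. With `restrictInRange` the
#' medians and histograms use only vertices inside the age range;
#' out-of-range vertices are tallied separately.
#'
#' @param fits output of [fitShapes()].
#' @param restrictInRange restrict medians/histograms to in-range vertices.
#' @param binWidth histogram bin width in weeks.
#' @return list with `n_u`, `n_bell`, `median_peak_u`, `median_peak_bell`,
#'   `n_out_of_range`, `breaks`, and per-shape bin `counts`.
#' @export
summarizePeaks <- function(fits, restrictInRange = TRUE, binWidth = 2) {
  stopifnot(all(c("shape", "vertex_age", "in_range") %in% colnames(fits)))
  sel <- fits$shape != "none"
  sub <- fits[sel, , drop = FALSE]
  nOut <- sum(!sub$in_range)
  if (restrictInRange) sub <- sub[sub$in_range, , drop = FALSE]
  med <- function(s) {
    v <- sub$vertex_age[sub$shape == s]
    if (length(v)) stats::median(v) else NA_real_
  }
  vIn <- fits$vertex_age[fits$in_range & !is.na(fits$vertex_age)]
  rng <- if (length(vIn)) range(vIn) else c(NA_real_, NA_real_)
  if (!nrow(sub) || !all(is.finite(rng))) {
    return(list(n_u = sum(fits$shape == "u"),
                n_bell = sum(fits$shape == "bell"),
                median_peak_u = NA_real_, median_peak_bell = NA_real_,
                n_out_of_range = nOut, breaks = numeric(),
                counts = list(u = integer(), bell = integer())))
  }
  breaks <- seq(floor(rng[1L]), ceiling(rng[2L]) + binWidth, by = binWidth)
  cnt <- function(s) {
    v <- sub$vertex_age[sub$shape == s]
    if (!length(v)) return(integer(length(breaks) - 1L))
    as.integer(table(cut(v, breaks, include.lowest = TRUE, right = FALSE)))
  }
  list(n_u = sum(fits$shape == "u"), n_bell = sum(fits$shape == "bell"),
       median_peak_u = med("u"), median_peak_bell = med("bell"),
       n_out_of_range = nOut, breaks = breaks,
       counts = list(u = cnt("u"), bell = cnt("bell")))
}
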