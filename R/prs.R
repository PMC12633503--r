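#' Compute standardized polygenic risk scores
#'
#' Weighted dosage sum per individual, `S_i = sum_j d_ij w_j`, then
#' standardized to mean 0 and SD 1 over the cohort.
#'
#' @param dosages individuals x variants matrix with values in `[0, 2]`;
#'   column names must match the weight table's variant ids.
#' @param weights data.table (variant_id, weight) or a named numeric
#'   vector.
#' @return list: `raw`, `z` (standardized scores).
#' @export
compute_prs <- function(dosages, weights) {
  dosages <- as.matrix(dosages)
  if (is.data.frame(weights) || is.data.table(weights)) {
    w <- setNames(as.data.table(weights)$weight,
                  as.data.table(weights)$variant_id)
  } else w <- weights
  if (is.null(names(w)) || is.null(colnames(dosages)))
    stop("dosage columns and weights must be named by variant id")
  missing <- setdiff(colnames(dosages), names(w))
  if (length(missing))
    stop("no weight for scored variant(s): ",
         paste(head(missing, 3), collapse = ", "))
  raw <- drop(dosages %*% w[colnames(dosages)])
  s <- sd(raw)
  if (!is.finite(s) || s == 0)
    stop("zero-variance scores; cannot standardize")
  list(raw = raw, z = (raw - mean(raw)) / s)
}

#' Logistic association of a score with a binary phenotype
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares,
#' convergence tolerance 1e-8, at most 50 iterations) of
#' `phenotype ~ score + covariates`. The score coefficient is the log-odds
#' change per score unit (per SD when given standardized scores).
#' Separation is reported with a flag.
#'
#' @param scores numeric vector (typically standardized).
#' @param phenotype 0/1 vector.
#' @param covariates optional numeric data.frame/matrix.
#' @return list: `beta`, `se`, `p`, `or`, `ci` (95%), `converged`,
#'   `separation`.
#' @export
logistic_association <- function(scores, phenotype, covariates = NULL) {
  stopifnot(length(scores) == length(phenotype),
            all(phenotype %in% c(0, 1)))
  if (sd(scores) == 0)
    stop("constant score; odds ratio undefined")
  df <- data.frame(y = phenotype, score = scores)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- suppressWarnings(
    glm(y ~ ., data = df, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 50)))
  beta <- coef(fit)["score"]
  se <- sqrt(diag(vcov(fit))["score"])
  fitted <- fit$fitted.values
  separation <- !fit$converged || any(fitted < 1e-8) || any(fitted > 1 - 1e-8)
  z <- beta / se
  list(beta = unname(beta), se = unname(se),
       p = unname(2 * stats::pnorm(-abs(z))),
       or = unname(exp(beta)),
       ci = unname(exp(beta + c(-1.96, 1.96) * se)),
       converged = fit$converged, separation = separation)
}

#' Decile odds ratios versus the lowest decile
#'
#' Individuals are cut into 10 deciles by score rank (ties broken by stable
#' order). For each decile d,
#' `OR_d = (cases_d * controls_1) / (controls_d * cases_1)` with a 95% CI
#' from the log-OR standard error `sqrt(sum 1/cell)`. Any zero cell
#' triggers the Haldane-Anscombe 0.5 correction, flagged per decile.
#'
#' @param scores numeric vector.
#' @param phenotype 0/1 vector.
#' @return data.table (decile, n, cases, controls, or, lo, hi,
#'   haldane).
#' @export
decile_odds_ratios <- function(scores, phenotype) {
  stopifnot(length(scores) == length(phenotype),
            all(phenotype %in% c(0, 1)), length(scores) >= 10)
  n <- length(scores)
  dec <- ceiling(rank(scores, ties.method = "first") * 10 / n)
  tab <- data.table(decile = dec, y = phenotype)[
    , .(n = .N, cases = sum(y), controls = sum(y == 0)), by = decile]
  setorder(tab, decile)
  c1 <- tab$cases[1]; k1 <- tab$controls[1]
  tab[, haldane := cases == 0 | controls == 0 | c1 == 0 | k1 == 0]
  tab[, c("or", "lo", "hi") := {
    a <- cases; b <- controls
    cc <- rep(c1, .N); kk <- rep(k1, .N)
    adj <- haldane
    a <- a + 0.5 * adj; b <- b + 0.5 * adj
    cc <- cc + 0.5 * adj; kk <- kk + 0.5 * adj
    or <- (a * kk) / (b * cc)
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / kk)
    list(or, exp(log(or) - 1.96 * se), exp(log(or) + 1.96 * se))
  }]
  tab[decile == 1, `:=`(or = 1, lo = NA_real_, hi = NA_real_)]
  tab[]
}
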