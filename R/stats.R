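#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation on pairwise-complete observations, with the
#' usual two-sided p-value from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2}
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values are
#'   dropped.
#' @return Named vector \code{c(r, p, n)}.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value, n = n)
}

# pairwise absolute-difference matrix, double-centered
dc_matrix <- function(x) {
  a <- abs(outer(x, x, "-"))
  a - outer(rowMeans(a), colMeans(a), "+") + mean(a)
}

#' Distance correlation
#'
#' Estimates the distance correlation between two numeric vectors from the
#' double-centered pairwise absolute-difference matrices A and B:
#' \eqn{dCov^2 = mean(A \circ B)}, \eqn{dVar^2} analogously, and
#' \eqn{dCor = dCov / \sqrt{dVar_x dVar_y}} (0 when either dVar is 0).
#' Distance correlation lies in [0, 1], is 0 only under independence (in the
#' population) and 1 when the vectors are identical up to an affine map.
#'
#' @param x,y Numeric vectors of equal length (n >= 4); pairs with missing
#'   values are dropped.
#' @return dCor in [0, 1].
#' @export
distance_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need >= 4 complete pairs", call. = FALSE)
  A <- dc_matrix(x)
  B <- dc_matrix(y)
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)
  if (dvarx <= 0 || dvary <= 0) return(0)
  # numerical guard: tiny negative dcov2 can arise from cancellation
  sqrt(max(dcov2, 0)) / (dvarx * dvary)^0.25
}

#' Permutation p-value for distance correlation
#'
#' Estimates \eqn{p = (1 + \#\{dCor_{perm} \ge dCor_{obs}\}) / (1 + n_{perm})}
#' by permuting y with a seeded generator. Deterministic given the seed.
#'
#' @param x,y Numeric vectors (complete cases used).
#' @param n_perm Number of permutations (>= 200).
#' @param seed Integer seed.
#' @return Named vector \code{c(dcor, p)}.
#' @export
dcc_permutation_p <- function(x, y, n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 200)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 complete pairs", call. = FALSE)
  A <- dc_matrix(x)
  B <- dc_matrix(y)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)  # invariant under permutation of y
  if (dvarx <= 0 || dvary <= 0)
    return(c(dcor = 0, p = 1))
  denom <- (dvarx * dvary)^0.25
  obs <- sqrt(max(mean(A * B), 0)) / denom
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    dc <- sqrt(max(mean(A * B[p, p]), 0)) / denom
    if (dc >= obs) exceed <- exceed + 1L
  }
  c(dcor = obs, p = (1 + exceed) / (1 + n_perm))
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Adjusts p-values by the Benjamini-Yekutieli step-up procedure, which
#' controls the false discovery rate under arbitrary dependence between
#' tests, and flags rejections at level \code{q}.
#'
#' @param pvals Numeric vector of raw p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with \code{adjusted} p-values and logical \code{reject}.
#' @export
by_fdr <- function(pvals, q = 0.05) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values outside [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(pvals, method = "BY")
  list(adjusted = adj, reject = !is.na(adj) & adj < q)
}

#' Mukaka category of a correlation magnitude
#'
#' Rule-of-thumb bins on the absolute coefficient: negligible [0, 0.3), low
#' [0.3, 0.5), moderate [0.5, 0.7), high [0.7, 0.9), very high [0.9, 1].
#'
#' @param coef Numeric vector of correlation coefficients.
#' @return Character vector of categories.
#' @export
mukaka_category <- function(coef) {
  as.character(cut(abs(coef), c(0, 0.3, 0.5, 0.7, 0.9, 1.0000001),
                   labels = c("negligible", "low", "moderate", "high", "very high"),
                   right = FALSE, include.lowest = TRUE))
}

#' Relevance flags and categories for a correlation screen
#'
#' A pair is relevant when its FDR-adjusted p-value is below \code{alpha} and
#' the absolute coefficient is at least \code{threshold}.
#'
#' @param screen Data frame with columns \code{pcc}, \code{pcc_p_adj} and
#'   (optionally) \code{dcc}, \code{dcc_p_adj}.
#' @param threshold Coefficient magnitude threshold (default 0.3).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return The screen with \code{relevant_pcc}, \code{relevant_dcc},
#'   \code{category_pcc}, \code{category_dcc} columns filled in.
#' @export
relevance_screen <- function(screen, threshold = 0.3, alpha = 0.05) {
  if ("pcc" %in% names(screen)) {
    screen$relevant_pcc <- !is.na(screen$pcc_p_adj) & screen$pcc_p_adj < alpha &
      abs(screen$pcc) >= threshold
    screen$category_pcc <- mukaka_category(screen$pcc)
  }
  if ("dcc" %in% names(screen) && !all(is.na(screen$dcc))) {
    screen$relevant_dcc <- !is.na(screen$dcc_p_adj) & screen$dcc_p_adj < alpha &
      abs(screen$dcc) >= threshold
    screen$category_dcc <- mukaka_category(screen$dcc)
  }
  screen
}

group_gender <- function(group) {
  ifelse(group %in% c("NF", "FDF"), "female",
         ifelse(group %in% c("NM", "FDM"), "male", NA_character_))
}

#' Run the GAW-acoustic correlation screen
#'
#' For each gender (females = NF + FDF, males = NM + FDM, healthy and
#' disordered merged), computes Pearson and (optionally) distance correlation
#' with permutation p-values for every GAW x acoustic parameter pair, then
#' applies Benjamini-Yekutieli FDR control separately within each
#' (gender x coefficient-type) family, and flags relevant pairs (adjusted
#' p < 0.05 and |coefficient| >= 0.3).
#'
#' @param params Cohort parameter table from \code{\link{extract_cohort}}
#'   (columns \code{subject_id}, \code{group}, parameter columns).
#' @param coefficients Which coefficients to compute: subset of
#'   \code{c("pcc", "dcc")}.
#' @param n_perm Permutations for the distance-correlation p-value.
#' @param seed Seed for the permutation streams.
#' @param threshold Relevance threshold on |coefficient|.
#' @param q FDR level.
#' @return Tidy data frame: one row per (gender, gaw_param, acoustic_param)
#'   with n, coefficients, raw/adjusted p-values, relevance flags and Mukaka
#'   categories.
#' @export
run_screen <- function(params, coefficients = c("pcc", "dcc"), n_perm = 1000,
                       seed = 1L, threshold = 0.3, q = 0.05) {
  coefficients <- match.arg(coefficients, several.ok = TRUE)
  schema <- parameter_schema()
  gaw_keys <- schema$key[schema$signal %in% c("gaw", "gaw_symmetry")]
  ac_keys <- schema$key[schema$signal == "acoustic"]
  gaw_keys <- intersect(gaw_keys, names(params))
  ac_keys <- intersect(ac_keys, names(params))
  gender <- group_gender(params$group)

  out <- list()
  for (g in c("female", "male")) {
    sub <- params[!is.na(gender) & gender == g, , drop = FALSE]
    if (nrow(sub) == 0) next
    n_complete <- sum(stats::complete.cases(sub[, c(gaw_keys, ac_keys)]))
    if (n_complete < 4)
      stop("too few subjects in the ", g, " group (need >= 4)", call. = FALSE)
    grid <- expand.grid(gaw_param = gaw_keys, acoustic_param = ac_keys,
                        stringsAsFactors = FALSE)
    res <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      x <- sub[[grid$gaw_param[i]]]
      y <- sub[[grid$acoustic_param[i]]]
      row <- data.frame(gender = g, gaw_param = grid$gaw_param[i],
                        acoustic_param = grid$acoustic_param[i],
                        n = sum(is.finite(x) & is.finite(y)),
                        pcc = NA_real_, pcc_p_raw = NA_real_,
                        dcc = NA_real_, dcc_p_raw = NA_real_)
      if ("pcc" %in% coefficients) {
        pc <- tryCatch(pearson(x, y), error = function(e) NULL)
        if (!is.null(pc)) { row$pcc <- pc[["r"]]; row$pcc_p_raw <- pc[["p"]] }
      }
      if ("dcc" %in% coefficients) {
        pair_seed <- (as.integer(seed) * 2654435L + i * 97L) %% .Machine$integer.max
        dc <- tryCatch(dcc_permutation_p(x, y, n_perm, seed = pair_seed),
                       error = function(e) NULL)
        if (!is.null(dc)) { row$dcc <- dc[["dcor"]]; row$dcc_p_raw <- dc[["p"]] }
      }
      res[[i]] <- row
    }
    res <- do.call(rbind, res)
    # one FDR family per gender per coefficient type
    res$pcc_p_adj <- if ("pcc" %in% coefficients) by_fdr(res$pcc_p_raw, q)$adjusted else NA_real_
    res$dcc_p_adj <- if ("dcc" %in% coefficients) by_fdr(res$dcc_p_raw, q)$adjusted else NA_real_
    out[[g]] <- relevance_screen(res, threshold = threshold, alpha = q)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-group norm tables
#'
#' Descriptive statistics per group and parameter: n (non-missing), minimum,
#' maximum, mean, median, sample standard deviation (n - 1), skewness
#' \eqn{g_1 = m_3 / m_2^{3/2}} and excess kurtosis \eqn{m_4/m_2^2 - 3}
#' (central moments with 1/n normalization). Standard deviation requires
#' n >= 2, skewness n >= 3, kurtosis n >= 4 (NA otherwise); skewness and
#' kurtosis are NA for constant columns.
#'
#' @param params Cohort parameter table.
#' @param groups Group labels to tabulate (default the four cohort groups).
#' @return Data frame: one row per (group, parameter).
#' @export
norm_table <- function(params, groups = c("NF", "FDF", "NM", "FDM")) {
  schema <- parameter_schema()
  keys <- intersect(schema$key, names(params))
  rows <- list()
  for (g in groups) {
    sub <- params[params$group == g, , drop = FALSE]
    for (k in keys) {
      x <- sub[[k]]
      x <- x[is.finite(x)]
      n <- length(x)
      m2 <- if (n > 0) mean((x - mean(x))^2) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        group = g, parameter = k, n = n,
        minimum = if (n > 0) min(x) else NA_real_,
        maximum = if (n > 0) max(x) else NA_real_,
        mean = if (n > 0) mean(x) else NA_real_,
        median = if (n > 0) stats::median(x) else NA_real_,
        std = if (n >= 2) stats::sd(x) else NA_real_,
        skewness = if (n >= 3 && m2 > 0) e1071::skewness(x, type = 1) else NA_real_,
        kurtosis = if (n >= 4 && m2 > 0) e1071::kurtosis(x, type = 1) else NA_real_)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
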