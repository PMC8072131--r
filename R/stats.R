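#' Wilcoxon rank-sum test of two samples
#'
#' Two-sided rank-sum test of a difference in location (the standard
#' test for skewed per-object metrics such as tortuosity, diameter and
#' eccentricity, summarized by medians). Ties receive midranks. When
#' `min(nA, nB) <= 8` the null distribution of the rank sum is enumerated
#' exhaustively over all assignments of the pooled values (exact even under
#' ties); otherwise the normal approximation with tie correction and
#' continuity correction is used. The two-sided p value is
#' `min(1, 2 min(P(W <= w), P(W >= w)))`.
#'
#' @param a,b numeric samples (both non-empty).
#' @param exact_max largest `min(nA, nB)` for which the exact enumeration is
#'   used.
#' @return one-row tibble (`stat_result` schema): `test`, `statistic`
#'   (rank sum of `a`), `p_value`, `method`, `n_a`, `n_b`.
#' @export
rank_sum_test <- function(a, b, exact_max = 8) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled) # midranks
  w <- sum(r[seq_len(na)])
  if (min(na, nb) <= exact_max) {
    # exhaustive enumeration of all C(na+nb, na) assignments
    idx <- utils::combn(na + nb, na)
    ws <- colSums(matrix(r[idx], nrow = na))
    p_le <- mean(ws <= w + 1e-9)
    p_ge <- mean(ws >= w - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    n <- na + nb
    mu <- na * (n + 1) / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  tibble::tibble(test = "wilcoxon_rank_sum", statistic = w, p_value = p,
                 method = method, n_a = na, n_b = nb)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum gap between the two empirical CDFs (used for comparing
#' vessel diameter distributions); the p value is the asymptotic Kolmogorov
#' distribution evaluated at the effective sample size.
#'
#' @param a,b numeric samples (both non-empty).
#' @return one-row tibble: `test`, `statistic` (D), `p_value`, `method`,
#'   `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  a <- sort(as.numeric(a)); b <- sort(as.numeric(b))
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  pts <- sort(unique(c(a, b)))
  fa <- findInterval(pts, a) / na
  fb <- findInterval(pts, b) / nb
  d <- max(abs(fa - fb))
  n_eff <- na * nb / (na + nb)
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  p <- min(1, max(0, p))
  tibble::tibble(test = "kolmogorov_smirnov", statistic = d, p_value = p,
                 method = "asymptotic", n_a = na, n_b = nb)
}

#' Two-way ANOVA (age x sex) with type-II sums of squares
#'
#' Effect-coded linear model `metric ~ age * sex` with type-II sums of
#' squares (robust to the mildly unbalanced designs of 4-6 animals per
#' group): F and p for the two main effects and their interaction. A design
#' cell that is empty while the interaction is requested raises a
#' rank-deficiency error naming the cell.
#'
#' @param data data frame with the factors and the metric.
#' @param metric metric column name (string).
#' @param factor_a,factor_b factor column names (default `"age"`, `"sex"`).
#' @return tibble: `effect`, `sum_sq`, `df`, `f_value`, `p_value`.
#' @export
two_way_anova <- function(data, metric, factor_a = "age", factor_b = "sex") {
  stopifnot(is.data.frame(data))
  for (cn in c(metric, factor_a, factor_b)) {
    if (!cn %in% names(data)) stop("missing column: ", cn, call. = FALSE)
  }
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    stop("each factor needs at least 2 levels", call. = FALSE)
  }
  tab <- table(fa, fb)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s",
                 factor_a, rownames(tab)[empty[1]],
                 factor_b, colnames(tab)[empty[2]]), call. = FALSE)
  }
  df <- data.frame(y = as.numeric(data[[metric]]), A = fa, B = fb)
  # RSS is invariant to the factor coding, so no explicit contrasts needed
  rss <- function(form) sum(lm(form, data = df)$residuals^2)
  # type-II SS by model comparison: each term adjusted for the others at or
  # below its order
  rss_full <- rss(y ~ A * B)
  rss_ab <- rss(y ~ A + B)
  ss <- c(rss(y ~ B) - rss_ab,   # A | B
          rss(y ~ A) - rss_ab,   # B | A
          rss_ab - rss_full)     # A:B | A, B
  ss <- pmax(ss, 0)
  dfs <- c(nlevels(fa) - 1, nlevels(fb) - 1,
           (nlevels(fa) - 1) * (nlevels(fb) - 1))
  df_res <- nrow(df) - nlevels(fa) * nlevels(fb)
  if (df_res < 1) {
    stop("no residual degrees of freedom for the interaction model",
         call. = FALSE)
  }
  ms_res <- rss_full / df_res
  eps <- 1e-12 * max(1, sum(df$y^2))
  if (ms_res > eps) {
    fv <- (ss / dfs) / ms_res
    pv <- stats::pf(fv, dfs, df_res, lower.tail = FALSE)
  } else {
    # zero-residual design: an effect with zero SS has F 0, any other is
    # unbounded and reported as p -> 0
    fv <- ifelse(ss <= eps, 0, Inf)
    pv <- ifelse(ss <= eps, 1, 0)
  }
  tibble::tibble(
    effect = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
    sum_sq = ss,
    df = dfs,
    f_value = fv,
    p_value = pv
  )
}

#' Post hoc multiple-comparison adjustment
#'
#' Sidak adjustment of `m` pairwise p values: `p' = 1 - (1 - p)^m`
#' (monotone in p, never below the raw p). For Tukey's all-pairs
#' comparisons use [tukey_posthoc()], which draws on the studentized range
#' and the ANOVA error term.
#'
#' @param p numeric vector of raw p values in `[0, 1]`.
#' @param method `"sidak"` or `"bonferroni"`.
#' @param m number of comparisons (defaults to `length(p)`).
#' @return adjusted p values, same length as `p`.
#' @examples
#' posthoc_adjust(0.05, m = 3) # 1 - 0.95^3 = 0.142625
#' @export
posthoc_adjust <- function(p, method = c("sidak", "bonferroni"),
                           m = length(p)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  switch(method,
    sidak = 1 - (1 - p)^m,
    bonferroni = pmin(1, p * m)
  )
}

#' Tukey honest significant differences for all group pairs
#'
#' Studentized-range-based all-pairs comparisons of group means using the
#' pooled ANOVA error term (via [stats::TukeyHSD()] on a one-way fit of the
#' group factor).
#'
#' @param data data frame; `metric` and `group` are column names.
#' @param metric,group column names (strings).
#' @return tibble: `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_posthoc <- function(data, metric, group) {
  df <- data.frame(y = as.numeric(data[[metric]]),
                   g = factor(data[[group]]))
  fit <- stats::aov(y ~ g, data = df)
  tk <- stats::TukeyHSD(fit)$g
  tibble::tibble(
    comparison = rownames(tk),
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"])
  )
}

#' Group-comparison battery for a metric table
#'
#' Runs the standard battery over a per-sample (or per-object) table with
#' `age` and `sex` factors: the two-way ANOVA with the chosen post hoc
#' adjustment of pairwise sex contrasts within age, and rank-sum tests per
#' age level. Emits a tidy long table of results labelled by comparison.
#'
#' @param data data frame with `age`, `sex` and the metric column.
#' @param metric metric column name.
#' @param posthoc `"sidak"` or `"tukey"`.
#' @return tibble of `stat_result` rows.
#' @export
compare_groups <- function(data, metric, posthoc = c("sidak", "tukey")) {
  posthoc <- match.arg(posthoc)
  out <- list()
  ages <- sort(unique(data$age))
  sexes <- sort(unique(data$sex))
  if (length(ages) >= 2 && length(sexes) >= 2 &&
      all(table(data$age, data$sex) > 0) &&
      nrow(data) > length(ages) * length(sexes)) {
    an <- two_way_anova(data, metric)
    out$anova <- dplyr::mutate(
      tibble::tibble(test = "two_way_anova", statistic = an$f_value,
                     p_value = an$p_value, method = "type II SS",
                     n_a = NA_integer_, n_b = NA_integer_),
      comparison = an$effect, adjustment = "none")
  }
  # sex contrast within each age
  pair_rows <- list()
  for (ag in ages) {
    sub <- data[data$age == ag, ]
    if (length(unique(sub$sex)) == 2) {
      s <- split(sub[[metric]], sub$sex)
      rs <- rank_sum_test(s[[1]], s[[2]])
      rs$comparison <- sprintf("%s vs %s at age %s",
                               names(s)[1], names(s)[2], ag)
      pair_rows[[length(pair_rows) + 1]] <- rs
    }
  }
  if (length(pair_rows) > 0) {
    pr <- dplyr::bind_rows(pair_rows)
    if (posthoc == "sidak") {
      pr$p_adjusted <- posthoc_adjust(pr$p_value, "sidak", m = nrow(pr))
      pr$adjustment <- "sidak"
    } else {
      tk <- tukey_posthoc(
        dplyr::mutate(data, grp = paste(.data$age, .data$sex, sep = "_")),
        metric, "grp")
      pr$p_adjusted <- NA_real_
      pr$adjustment <- "tukey (see tukey_posthoc table)"
      out$tukey <- dplyr::mutate(
        tibble::tibble(test = "tukey_hsd", statistic = tk$diff,
                       p_value = tk$p_adj, method = "studentized range",
                       n_a = NA_integer_, n_b = NA_integer_),
        comparison = tk$comparison, adjustment = "tukey")
    }
    out$pairwise <- pr
  }
  dplyr::bind_rows(out)
}
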