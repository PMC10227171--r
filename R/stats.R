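#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject ANOVA for one or two repeated factors, computed from the
#' standard sums-of-squares decomposition on the participant x cell means
#' (trials are averaged per participant and cell first). Each effect is
#' tested against its own participant-by-effect interaction; sphericity is
#' addressed with the Greenhouse-Geisser epsilon estimated from the
#' covariance of the orthonormalized condition contrasts, and effect sizes
#' are partial eta squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long tibble with one or more rows per participant x cell.
#' @param dv Name of the dependent-variable column (string).
#' @param id Name of the participant-identifier column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param correction `"GG"` (default) reports p values from the
#'   Greenhouse-Geisser-corrected degrees of freedom for every effect;
#'   `"none"` uses the uncorrected dfs. Both corrected and uncorrected p
#'   values are always present in the result table.
#' @return An object of class `rm_anova`; see [tidy.rm_anova()] for the
#'   effect table (F, dfs, epsilon, p values, partial eta squared).
#' @examples
#' d <- tidyr::expand_grid(id = factor(1:6), speed = c(3, 4, 5))
#' d$y <- rnorm(nrow(d)) + d$speed
#' rm_anova(d, dv = "y", id = "id", within = "speed")
#' @export
rm_anova <- function(data, dv, id, within, correction = c("GG", "none")) {
  correction <- match.arg(correction)
  stopifnot(is.character(dv), is.character(id), is.character(within),
            length(within) %in% 1:2)
  check_columns(data, c(dv, id, within), "data")
  data <- as_tibble(data)
  data[[id]] <- as.character(data[[id]])
  for (w in within) data[[w]] <- as.character(data[[w]])

  cells <- data %>%
    group_by(across(dplyr::all_of(c(id, within)))) %>%
    summarise(.y = mean(.data[[dv]]), .groups = "drop")
  if (any(!is.finite(cells$.y))) {
    stop("non-finite cell means in `", dv, "`", call. = FALSE)
  }

  a_lev <- sort(unique(cells[[within[1]]]))
  b_lev <- if (length(within) == 2) sort(unique(cells[[within[2]]])) else ""
  ids <- sort(unique(cells[[id]]))
  n <- length(ids); a <- length(a_lev); b <- length(b_lev)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)

  # participant x cell matrix, A varying slowest, B fastest
  grid <- tidyr::expand_grid(.a = a_lev, .b = b_lev)
  Y <- matrix(NA_real_, n, a * b, dimnames = list(ids, NULL))
  for (k in seq_len(nrow(grid))) {
    if (b > 1) {
      sub <- cells[cells[[within[1]]] == grid$.a[k] &
                     cells[[within[2]]] == grid$.b[k], ]
    } else {
      sub <- cells[cells[[within[1]]] == grid$.a[k], ]
    }
    v <- sub$.y[match(ids, sub[[id]])]
    if (anyNA(v)) {
      miss <- ids[which(is.na(v))[1]]
      stop("participant ", miss, " is missing cell ", within[1], "=",
           grid$.a[k],
           if (b > 1) paste0(", ", within[2], "=", grid$.b[k]) else "",
           call. = FALSE)
    }
    Y[, k] <- v
  }

  g <- mean(Y)
  m_s <- rowMeans(Y)
  idx_a <- rep(seq_len(a), each = b)
  idx_b <- rep(seq_len(b), times = a)
  m_sa <- t(apply(Y, 1, function(r) tapply(r, idx_a, mean)))
  m_sb <- t(apply(Y, 1, function(r) tapply(r, idx_b, mean)))
  if (a == 1) m_sa <- matrix(m_sa, ncol = 1)
  if (b == 1) m_sb <- matrix(m_sb, ncol = 1)
  m_a <- colMeans(m_sa); m_b <- colMeans(m_sb)
  m_ab <- matrix(colMeans(Y), nrow = a, byrow = TRUE)

  S <- cov(Y)
  onb <- function(k) { # orthonormal contrast basis, k x (k-1)
    if (k == 1) return(matrix(numeric(0), 1, 0))
    q <- stats::contr.helmert(k)
    sweep(q, 2, sqrt(colSums(q^2)), "/")
  }
  unit <- function(k) matrix(rep(1 / sqrt(k), k), k, 1)
  gg_eps <- function(C) {
    k <- ncol(C)
    if (k <= 1) return(1)
    M <- t(C) %*% S %*% C
    sum(diag(M))^2 / (k * sum(M^2))
  }

  effects <- list()
  # factor A
  SS_A <- n * b * sum((m_a - g)^2)
  SS_sA <- b * sum(sweep(sweep(m_sa, 1, m_s), 2, m_a - g)^2)
  effects[[within[1]]] <- list(
    ss = SS_A, ss_err = SS_sA, df1 = a - 1, df2 = (a - 1) * (n - 1),
    eps = gg_eps(kronecker(onb(a), unit(b)))
  )
  if (b > 1) {
    SS_B <- n * a * sum((m_b - g)^2)
    SS_sB <- a * sum(sweep(sweep(m_sb, 1, m_s), 2, m_b - g)^2)
    effects[[within[2]]] <- list(
      ss = SS_B, ss_err = SS_sB, df1 = b - 1, df2 = (b - 1) * (n - 1),
      eps = gg_eps(kronecker(unit(a), onb(b)))
    )
    inter <- outer(m_a - g, m_b - g, "+") + g # m_a + m_b - g as a x b
    SS_AB <- n * sum((m_ab - inter)^2)
    resid <- Y - m_sa[, idx_a] - m_sb[, idx_b] -
      matrix(as.vector(t(m_ab)), n, a * b, byrow = TRUE) +
      m_s + matrix(m_a[idx_a] + m_b[idx_b] - g, n, a * b, byrow = TRUE)
    SS_sAB <- sum(resid^2)
    effects[[paste(within, collapse = ":")]] <- list(
      ss = SS_AB, ss_err = SS_sAB,
      df1 = (a - 1) * (b - 1), df2 = (a - 1) * (b - 1) * (n - 1),
      eps = gg_eps(kronecker(onb(a), onb(b)))
    )
  }

  table <- purrr::imap(effects, function(e, nm) {
    ms <- e$ss / e$df1
    ms_err <- e$ss_err / e$df2
    f <- if (ms_err > 0) ms / ms_err else if (ms == 0) 0 else Inf
    if (e$ss == 0) f <- 0
    p_unc <- pf(f, e$df1, e$df2, lower.tail = FALSE)
    p_gg <- pf(f, e$eps * e$df1, e$eps * e$df2, lower.tail = FALSE)
    tibble(
      effect = nm, ss = e$ss, ss_error = e$ss_err,
      df_num = e$df1, df_den = e$df2, F = f, epsilon = e$eps,
      df_num_gg = e$eps * e$df1, df_den_gg = e$eps * e$df2,
      p_uncorrected = p_unc, p_gg = p_gg,
      p = if (correction == "GG") p_gg else p_unc,
      partial_eta_sq = if (e$ss + e$ss_err > 0) e$ss / (e$ss + e$ss_err) else 0
    )
  }) %>% bind_rows()

  structure(
    list(table = table, dv = dv, id = id, within = within, n = n,
         n_cells = a * b, correction = correction, cell_means = Y),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$n, " participants, dv = ", x$dv,
      ", ", x$correction, " correction)\n\n", sep = "")
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-20s F(%.2f, %.2f) = %.2f, p = %.4g, eps = %.3f, pes = %.3f\n",
                tb$effect[i], tb$df_num_gg[i], tb$df_den_gg[i], tb$F[i],
                tb$p[i], tb$epsilon[i], tb$partial_eta_sq[i]))
  }
  invisible(x)
}

#' Tidy an rm_anova object
#'
#' @param x An [rm_anova()] object.
#' @param ... Unused.
#' @return A tibble with one row per effect: sums of squares, F, uncorrected
#'   and Greenhouse-Geisser dfs, epsilon, p values and partial eta squared.
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @rdname tidy.rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(n_participants = x$n, n_cells = x$n_cells, dv = x$dv,
         correction = x$correction)
}

#' Holm step-down adjustment of p values
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values (monotone, capped at 1) in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.03)) # 0.03 0.04 0.04
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "holm")
}

#' Pairwise within-subject contrasts
#'
#' Paired t tests between all level pairs of one within-subject factor
#' (participant cell means, averaging over any other factors), with
#' Holm-adjusted (default) or Bonferroni-adjusted p values.
#'
#' @param data Long tibble.
#' @param dv,id Column names of the dependent variable and participant id.
#' @param factor Column name of the factor to contrast.
#' @param adjust Multiplicity adjustment.
#' @return A tibble: `contrast`, `estimate` (mean difference), `t`, `df`,
#'   `p_raw`, `p_adjusted`.
#' @export
pairwise_contrasts <- function(data, dv, id, factor,
                               adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  check_columns(data, c(dv, id, factor), "data")
  means <- data %>%
    group_by(across(dplyr::all_of(c(id, factor)))) %>%
    summarise(.y = mean(.data[[dv]]), .groups = "drop")
  levs <- sort(unique(means[[factor]]))
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    w <- tidyr::pivot_wider(means, names_from = dplyr::all_of(factor),
                            values_from = ".y")
    d <- w[[as.character(pr[1])]] - w[[as.character(pr[2])]]
    d <- d[!is.na(d)]
    tt <- t.test(d)
    tibble(contrast = paste(pr[1], "-", pr[2]),
           estimate = mean(d), t = unname(tt$statistic),
           df = unname(tt$parameter), p_raw = tt$p.value)
  }) %>% bind_rows()
  rows$p_adjusted <- p.adjust(rows$p_raw, method = adjust)
  rows
}

#' Exploratory regression of TTC prediction timing on response time
#'
#' Ordinary least squares of the relative TTC prediction (%) on the
#' perturbation response time (saccadic or button, s), fitted separately
#' per speed condition on correct, valid perturbation trials. A positive
#' slope means later responses go with later (larger) TTC predictions.
#'
#' @param scores Trial-score tibble ([score_trials()] / [run_experiment()]).
#' @param by Grouping column (default `"speed"`).
#' @return A tibble per group: `n`, `slope` (%/s), `intercept`, `r`
#'   (Pearson), `p` (slope test).
#' @export
rt_ttc_regression <- function(scores, by = "speed") {
  check_columns(scores, c("valid", "correct", "relative_ttc", by), "scores")
  rt <- dplyr::coalesce(
    if ("saccadic_rt" %in% names(scores)) scores$saccadic_rt else NA_real_,
    if ("perturbation_rt" %in% names(scores)) scores$perturbation_rt else NA_real_
  )
  scores$.rt <- rt
  use <- scores %>%
    filter(.data$valid, .data$correct, !is.na(.data$.rt),
           !is.na(.data$relative_ttc))
  use %>%
    group_by(across(dplyr::all_of(by))) %>%
    summarise(.fit = list({
      if (dplyr::n() < 3) stop("need at least 3 trials per group", call. = FALSE)
      if (sd(.data$.rt) == 0) stop("response times are constant; slope undefined",
                                   call. = FALSE)
      fit <- lm(relative_ttc ~ .rt, data = dplyr::pick(dplyr::everything()))
      sm <- summary(fit)
      tibble(n = length(fit$residuals),
             slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
             r = sign(coef(fit)[[2]]) * sqrt(sm$r.squared),
             p = sm$coefficients[2, 4])
    }), .groups = "drop") %>%
    tidyr::unnest(".fit")
}
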