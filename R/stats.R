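#' Repeated-measures ANOVA on a zone-summary table
#'
#' Fits a within-subject ANOVA with one or two within-subject factors on a
#' complete balanced table of per-participant cell means (e.g. average
#' microsaccade rate per zone and condition). Each effect is tested
#' against its own participant-by-effect interaction stratum, the
#' classical univariate approach for this design; a Greenhouse-Geisser
#' correction of the degrees of freedom is available for effects with more
#' than two levels.
#'
#' @param data A tibble in long format: one row per participant x cell.
#' @param dv Name of the response column (character).
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param subject Name of the participant identifier column (default
#'   `"participant"`).
#' @param sphericity `"none"` (classical univariate F) or
#'   `"greenhouse_geisser"` (epsilon-adjusted df and p).
#' @return An object of class `rm_anova`: list with `anova` (tibble:
#'   `effect`, `df_num`, `df_den`, `statistic`, `p.value`, and with the
#'   correction `epsilon`, `df_num_adj`, `df_den_adj`, `p.adj`), `means`
#'   (per-cell means and SEs) and the call parameters. Use [tidy()] /
#'   [glance()] for tibble output.
#' @examples
#' tab <- tidyr::expand_grid(participant = paste0("P", 1:6),
#'                           condition = c("a", "b"))
#' tab$y <- stats::rnorm(nrow(tab)) + (tab$condition == "b")
#' rm_anova(tab, "y", "condition")
#' @export
rm_anova <- function(data, dv, within, subject = "participant",
                     sphericity = c("none", "greenhouse_geisser")) {
  sphericity <- match.arg(sphericity)
  stopifnot(length(within) %in% 1:2)
  cols <- c(dv, within, subject)
  if (!all(cols %in% names(data))) {
    stop("Missing column(s): ",
         paste(setdiff(cols, names(data)), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    y = data[[dv]],
    subject = factor(data[[subject]])
  )
  for (i in seq_along(within)) df[[within[i]]] <- factor(data[[within[i]]])
  # balance: every subject x cell combination exactly once
  cell_counts <- table(df$subject,
                       interaction(df[within], drop = FALSE))
  if (any(cell_counts != 1)) {
    stop("Design is not complete and balanced: every participant must ",
         "contribute exactly one value per cell.", call. = FALSE)
  }

  rhs <- paste(within, collapse = " * ")
  err <- paste0("Error(subject/(", rhs, "))")
  form <- stats::as.formula(paste("y ~", rhs, "+", err))
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)

  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    effs <- trimws(rownames(tab))
    for (j in seq_along(effs)) {
      if (effs[j] == "Residuals") next
      resid_row <- which(effs == "Residuals")
      fv <- tab$`F value`[j]
      pv <- tab$`Pr(>F)`[j]
      if (tab$`Sum Sq`[j] <= 1e-12 * max(sum(tab$`Sum Sq`), 1)) {
        fv <- 0  # no effect variance at all: define F = 0, p = 1
        pv <- 1
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        effect = gsub("`", "", effs[j]),
        df_num = tab$Df[j],
        df_den = tab$Df[resid_row],
        statistic = fv,
        p.value = pv
      )
    }
  }
  an <- dplyr::bind_rows(rows)

  if (sphericity == "greenhouse_geisser") {
    eps <- vapply(an$effect, function(e) gg_epsilon(df, e, within),
                  numeric(1), USE.NAMES = FALSE)
    an$epsilon <- eps
    an$df_num_adj <- an$df_num * eps
    an$df_den_adj <- an$df_den * eps
    an$p.adj <- stats::pf(an$statistic, an$df_num_adj, an$df_den_adj,
                          lower.tail = FALSE)
  }

  means <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(within))) |>
    dplyr::summarise(
      mean = mean(.data$y),
      se = stats::sd(.data$y) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    )

  structure(list(anova = an, means = means, dv = dv, within = within,
                 subject = subject, sphericity = sphericity),
            class = "rm_anova")
}

# Greenhouse-Geisser epsilon for one effect: project the subject x cell
# matrix onto the effect's orthonormal contrast space and apply
# eps = tr(M)^2 / (d * tr(M^2)) to the projected covariance.
gg_epsilon <- function(df, effect, within) {
  facs <- strsplit(effect, ":", fixed = TRUE)[[1]]
  # build the subject x cell matrix in a deterministic cell order
  lv <- lapply(within, function(w) levels(df[[w]]))
  names(lv) <- within
  grid <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE)
  subj <- levels(df$subject)
  X <- matrix(NA_real_, length(subj), nrow(grid))
  key_data <- do.call(paste, c(df[within], sep = "\r"))
  key_grid <- do.call(paste, c(grid, sep = "\r"))
  for (i in seq_along(subj)) {
    sel <- df$subject == subj[i]
    X[i, ] <- df$y[sel][match(key_grid, key_data[sel])]
  }
  contr <- function(k) {
    if (k == 1) return(matrix(1, 1, 1))
    qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
  }
  C <- matrix(1, 1, 1)
  for (w in within) {
    k <- length(lv[[w]])
    Cw <- if (w %in% facs) contr(k) else matrix(1 / sqrt(k), k, 1)
    C <- C %x% Cw
  }
  # expand.grid varies the first factor fastest; the Kronecker order above
  # varies the last factor fastest, so align by reordering the columns
  ord <- do.call(order, lapply(seq_along(within),
                               function(i) match(grid[[i]], lv[[i]])))
  M <- crossprod(C, stats::cov(X[, ord, drop = FALSE]) %*% C)
  d <- ncol(C)
  if (d <= 1) return(1)
  # sample epsilon, clamped to its theoretical range [1/d, 1]
  min(1, max(1 / d, (sum(diag(M)))^2 / (d * sum(M * M))))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", paste(x$within, collapse = " x "),
      ", within-subject)\n", sep = "")
  print(as.data.frame(x$anova), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return The per-effect ANOVA table as a tibble.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$anova

#' @rdname tidy.rm_anova
#' @return For `glance()`, a one-row tibble with the design size and the
#'   smallest effect p-value.
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    n_effects = nrow(x$anova),
    n_cells = nrow(x$means),
    min_p = min(x$anova$p.value)
  )
}

#' Paired t-test on per-participant values
#'
#' Classical paired t on the differences `x - y`; errors on zero-variance
#' differences rather than returning an infinite statistic.
#'
#' @param x,y Numeric vectors of equal length (one value per participant).
#' @return A tibble `statistic` (t), `df`, `p.value`, `estimate` (mean
#'   difference).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("`x` and `y` must have equal length >= 2.", call. = FALSE)
  }
  d <- x - y
  if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, mean(abs(d)))) {
    stop("Differences have (near-)zero variance; the paired t statistic ",
         "is degenerate.", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = ht$p.value,
                 estimate = unname(ht$estimate))
}

#' Post hoc pairwise comparisons with letter groupings
#'
#' All pairwise within-subject (paired-t) comparisons between the levels
#' of a factor, with optional Holm correction, plus a compact letter
#' display: levels sharing a letter are not significantly different at
#' `alpha`.
#'
#' @param data Long tibble: one row per participant x level.
#' @param dv,level,subject Column names for the response, the factor and
#'   the participant id.
#' @param correction `"holm"` (default) or `"none"`.
#' @param alpha Significance level for the letter grouping (default 0.05).
#' @return A list with `comparisons` (tibble `level1`, `level2`,
#'   `statistic`, `df`, `p.value`, `p.adj`) and `letters` (tibble `level`,
#'   `mean`, `se`, `letters`).
#' @export
posthoc_pairwise <- function(data, dv, level, subject = "participant",
                             correction = c("holm", "none"),
                             alpha = 0.05) {
  correction <- match.arg(correction)
  levs <- unique(as.character(data[[level]]))
  if (length(levs) < 2) stop("Need at least 2 levels.", call. = FALSE)
  wide <- lapply(levs, function(l) {
    sel <- data[[level]] == l
    v <- data[[dv]][sel][order(data[[subject]][sel])]
    v
  })
  names(wide) <- levs
  pairs <- utils::combn(levs, 2)
  cmp <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    # zero-variance differences: identical levels get t = 0 / p = 1, a
    # constant nonzero shift is unambiguously different (p = 0)
    tt <- tryCatch(paired_t(wide[[a]], wide[[b]]), error = function(e) {
      md <- mean(wide[[a]] - wide[[b]])
      tibble::tibble(statistic = if (md == 0) 0 else sign(md) * Inf,
                     df = length(wide[[a]]) - 1,
                     p.value = if (md == 0) 1 else 0)
    })
    tibble::tibble(level1 = a, level2 = b, statistic = tt$statistic,
                   df = tt$df, p.value = tt$p.value)
  })
  cmp$p.adj <- stats::p.adjust(cmp$p.value, method =
                                 if (correction == "holm") "holm" else "none")
  letters_tab <- letter_groups(levs, cmp, alpha)
  means <- data |>
    dplyr::group_by(level = .data[[level]]) |>
    dplyr::summarise(mean = mean(.data[[dv]]),
                     se = stats::sd(.data[[dv]]) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(level = as.character(.data$level))
  letters_tab <- dplyr::left_join(means, letters_tab, by = "level")
  list(comparisons = cmp, letters = letters_tab)
}

# Compact letter display: enumerate maximal level subsets whose pairs are
# all non-significant and assign one letter per subset.
letter_groups <- function(levs, cmp, alpha) {
  k <- length(levs)
  different <- matrix(FALSE, k, k, dimnames = list(levs, levs))
  sig <- cmp$p.adj < alpha
  for (j in seq_len(nrow(cmp))) {
    if (sig[j]) {
      different[cmp$level1[j], cmp$level2[j]] <- TRUE
      different[cmp$level2[j], cmp$level1[j]] <- TRUE
    }
  }
  subsets <- list()
  for (size in k:1) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      if (size == 1 || !any(different[idx, idx])) {
        covered <- any(vapply(subsets, function(s) all(idx %in% s),
                              logical(1)))
        if (!covered) subsets[[length(subsets) + 1]] <- idx
      }
    }
  }
  lab <- rep("", k)
  for (s in seq_along(subsets)) {
    lab[subsets[[s]]] <- paste0(lab[subsets[[s]]], letters[s])
  }
  tibble::tibble(level = levs, letters = lab)
}
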