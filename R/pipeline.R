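## Cohort I/O, orchestration of the estimators over a cohort table, group
## statistics (Kruskal-Wallis omnibus, Dunn post-hoc with Holm adjustment,
## Kolmogorov-Smirnov normality report), and the command-line surface.

cohort_cols <- c("patient_id", "lesion_id", "group", "time_days", "volume_cm3")

#' Read a cohort CSV
#'
#' Expected schema: `patient_id,lesion_id,group,time_days,volume_cm3`
#' (comma-separated, dot decimal, header required). Rows may arrive in any
#' order; they are sorted by lesion and time. Non-positive volumes and
#' duplicated times within a lesion are parse errors naming the offending
#' lesion.
#'
#' @param path CSV file path.
#' @return A `cohort_table` data.frame.
#' @export
read_cohort_csv <- function(path) {
  bm_assert(file.exists(path), "bm_parse_error",
            sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  bm_assert(all(cohort_cols %in% names(df)), "bm_parse_error",
            sprintf("header must contain: %s",
                    paste(cohort_cols, collapse = ",")))
  df <- df[cohort_cols]
  bm_assert(is.numeric(df$time_days) && is.numeric(df$volume_cm3),
            "bm_parse_error", "time_days and volume_cm3 must be numeric")
  bad <- unique(df$lesion_id[!is.finite(df$volume_cm3) | df$volume_cm3 <= 0])
  if (length(bad)) {
    bm_error("bm_parse_error",
             sprintf("non-positive volumes in lesion(s): %s",
                     paste(bad, collapse = ", ")))
  }
  df <- df[order(df$lesion_id, df$time_days), ]
  dup <- unlist(lapply(split(df$time_days, df$lesion_id),
                       function(t) any(diff(t) <= 0)))
  if (any(dup)) {
    bm_error("bm_parse_error",
             sprintf("non-increasing/duplicated times in lesion(s): %s",
                     paste(names(dup)[dup], collapse = ", ")))
  }
  rownames(df) <- NULL
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort CSV
#'
#' @param x A `cohort_table` data.frame or a list of [volume_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  if (!is.data.frame(x)) x <- cohort_table_from_series(x)
  write.csv(x[cohort_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a list of volume series to a cohort table
#' @param series List of [volume_series()].
#' @return A `cohort_table` data.frame.
#' @export
cohort_table_from_series <- function(series) {
  rows <- lapply(series, function(s) {
    data.frame(patient_id = s$patient_id, lesion_id = s$lesion_id,
               group = s$group, time_days = s$times, volume_cm3 = s$volumes,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Split a cohort table into volume series
#' @param table A `cohort_table`.
#' @return Named list of [volume_series()].
#' @export
as_volume_series <- function(table) {
  out <- lapply(split(table, table$lesion_id), function(d) {
    d <- d[order(d$time_days), ]
    volume_series(d$lesion_id[1], d$group[1], d$time_days, d$volume_cm3,
                  patient_id = d$patient_id[1])
  })
  out[unique(table$lesion_id)]
}

## First three strictly-increasing measurements of a series (the clinical
## three-point analysis uses exactly three), or NULL if none exist.
first_growing_triple <- function(series) {
  t <- series$times
  v <- series$volumes
  keep <- c(TRUE, diff(cummax(v)) > 0)  # greedy strictly-increasing subsequence
  t <- t[keep]
  v <- v[keep]
  if (length(t) < 3L) return(NULL)
  three_point_record(t[1:3], v[1:3], lesion_id = series$lesion_id)
}

#' Dunn's pairwise rank test
#'
#' Post-hoc comparisons after a Kruskal-Wallis omnibus: pairwise z statistics
#' on mean ranks with the usual tie correction, two-sided p-values, Holm
#' adjusted by default.
#'
#' @param x Numeric response.
#' @param g Group factor.
#' @param p_adjust_method Passed to [stats::p.adjust()] (default `"holm"`).
#' @return Data.frame with columns `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_test <- function(x, g, p_adjust_method = "holm") {
  g <- factor(g)
  ok <- !is.na(x)
  x <- x[ok]
  g <- droplevels(g[ok])
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2L)
  z <- apply(pairs, 2L, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[p[1]] + 1 / n[p[2]]))
    (rbar[p[1]] - rbar[p[2]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z),
             p_value = as.numeric(p),
             p_adjusted = p.adjust(p, method = p_adjust_method),
             row.names = NULL)
}

#' Run the full cohort analysis
#'
#' Per lesion: three-point exponent on the first three strictly increasing
#' measurements; optionally a perturbation screen, excluding sensitive
#' lesions. Per group: summary quartiles, a Kolmogorov-Smirnov normality
#' report (computed but never gating the nonparametric comparison), and a
#' group-sweep exponent. Across groups: Kruskal-Wallis omnibus plus Dunn
#' pairwise tests with Holm adjustment. Groups with fewer than 2 usable
#' lesions are excluded from comparisons with a warning.
#'
#' @param table A `cohort_table` (see [read_cohort_csv()]).
#' @param screen Run [perturbation_screen()] per lesion and drop lesions
#'   failing the consistency criterion (default FALSE).
#' @param screen_reps,screen_noise Screen parameters (defaults 200, 0.05).
#' @param sweep Run [sweep_group_beta()] per group (default TRUE).
#' @param n_beta,n_v0,n_v1 Sweep grid resolutions; defaults are reduced from
#'   the full 300/500/500 analysis grids to keep interactive runs fast.
#' @param seed Optional integer seed (screen randomness).
#' @return List with `betas` (per-lesion data.frame), `group_summary`,
#'   `kruskal` (htest or NULL), `pairwise` (Dunn table or NULL),
#'   `ks_normality`, `sweeps` (named list of `group_sweep_result`),
#'   `excluded` (character).
#' @export
run_cohort_analysis <- function(table, screen = FALSE, screen_reps = 200L,
                                screen_noise = 0.05, sweep = TRUE,
                                n_beta = 121L, n_v0 = 80L, n_v1 = 80L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  series <- as_volume_series(table)
  rows <- list()
  records <- list()
  excluded <- character()
  for (s in series) {
    rec <- first_growing_triple(s)
    if (is.null(rec)) {
      excluded <- c(excluded, sprintf("%s: no growing triple", s$lesion_id))
      next
    }
    est <- tryCatch(solve_three_point_beta(rec), bm_error = function(e) NULL)
    if (is.null(est)) {
      excluded <- c(excluded, sprintf("%s: solver failure", s$lesion_id))
      next
    }
    keep <- TRUE
    scr <- NA
    if (screen) {
      scr <- tryCatch(
        perturbation_screen(rec, n_reps = screen_reps,
                            max_rel_err = screen_noise)$passed,
        bm_error = function(e) FALSE)
      keep <- isTRUE(scr)
      if (!keep) excluded <- c(excluded,
                               sprintf("%s: failed sensitivity screen",
                                       s$lesion_id))
    }
    if (keep) {
      rows[[length(rows) + 1L]] <-
        data.frame(lesion_id = s$lesion_id, group = s$group, beta = est$beta,
                   method = est$method, residual = est$residual,
                   screen_passed = scr, stringsAsFactors = FALSE)
      records[[s$lesion_id]] <- rec
    }
  }
  betas <- do.call(rbind, rows)
  bm_assert(!is.null(betas) && nrow(betas) > 0, "bm_validation_error",
            "no usable lesions in the cohort")

  grp <- split(betas$beta, betas$group)
  group_summary <- do.call(rbind, lapply(names(grp), function(g) {
    q <- quantile(grp[[g]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(grp[[g]]), q1 = q[1], median = q[2],
               q3 = q[3], stringsAsFactors = FALSE)
  }))

  usable <- names(grp)[lengths(grp) >= 2L]
  dropped <- setdiff(names(grp), usable)
  if (length(dropped)) {
    warning(sprintf("group(s) with < 2 lesions excluded from comparisons: %s",
                    paste(dropped, collapse = ", ")))
  }
  kw <- pw <- NULL
  if (length(usable) >= 2L) {
    sub <- betas[betas$group %in% usable, ]
    kw <- kruskal.test(sub$beta, factor(sub$group))
    pw <- dunn_test(sub$beta, sub$group)
  }
  ks <- do.call(rbind, lapply(names(grp), function(g) {
    x <- grp[[g]]
    p <- if (length(x) >= 3L && sd(x) > 0) {
      suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
    } else NA_real_
    data.frame(group = g, ks_p_value = p, stringsAsFactors = FALSE)
  }))

  sweeps <- NULL
  if (sweep) {
    sweeps <- lapply(split(records, betas$group), function(rs) {
      sweep_group_beta(unname(rs), n_beta = n_beta, n_v0 = n_v0, n_v1 = n_v1)
    })
  }
  list(betas = betas, group_summary = group_summary, kruskal = kw,
       pairwise = pw, ks_normality = ks, sweeps = sweeps, excluded = excluded)
}
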