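# Cohort-level reliability report: per feature, within-session ICC(3,k) on
# the first session's events and across-session repeated-measures ANOVA on
# per-animal session means.

#' Reliability analysis of a session feature table
#'
#' The central fitting function of the package. For each feature it
#' computes:
#' \itemize{
#'   \item within-session reliability: ICC(3,k) over the first
#'     `n_events` successive events of the first session, animals as
#'     subjects, events as measurements ([icc3k()]);
#'   \item across-session reliability (when the table holds two or more
#'     sessions): a one-way repeated-measures ANOVA on per-animal session
#'     means, each mean an average of `n_events` successive events
#'     ([rm_anova()]), with per-session mean and SD computed over the same
#'     per-animal means.
#' }
#' Animals with fewer than `n_events` events for a feature are excluded for
#' that feature with a warning (no imputation); fewer than two remaining
#' animals is an error.
#'
#' @param table long-format feature table (`animal_id`, `session_id`,
#'   `event_index`, `feature`, `value`), e.g. from [cohort_study()] or
#'   [read_feature_table()].
#' @param n_events events per session entering the ICC and the session
#'   means.
#' @param alpha significance criterion for flagging session effects.
#' @param features features to analyse; default all present, in canonical
#'   order.
#' @return An object of class `stuc_reliability`: a list with one element
#'   per feature (`icc`, `anova` or `NULL`, `session_means`, `session_sds`,
#'   `n_animals`, `significant`), plus `alpha`, `n_events`, `sessions`.
#' @seealso [report_json()], [report_markdown()]
#' @export
stuc_reliability <- function(table, n_events = 5, alpha = 0.05,
                             features = NULL) {
  cols <- c("animal_id", "session_id", "event_index", "feature", "value")
  if (!all(cols %in% names(table))) {
    stop("feature table must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) == 0) stop("empty feature table", call. = FALSE)
  validate_feature_table(table)
  present <- intersect(stuc_features(), unique(table$feature))
  present <- c(present, setdiff(unique(table$feature), present))
  if (is.null(features)) features <- present
  sessions <- sort(unique(table$session_id))
  first_session <- sessions[1]

  per_feature <- list()
  for (f in features) {
    sub <- table[table$feature == f, ]
    # animals x events matrix for the first session
    s1 <- sub[sub$session_id == first_session, ]
    s1 <- s1[order(s1$animal_id, s1$event_index), ]
    counts <- table(s1$animal_id)
    short <- names(counts)[counts < n_events]
    if (length(short) > 0) {
      warning("feature ", f, ": excluding animal(s) with fewer than ",
              n_events, " events: ", paste(short, collapse = ", "),
              call. = FALSE)
    }
    keep <- names(counts)[counts >= n_events]
    if (length(keep) < 2) {
      stop("feature ", f, ": fewer than 2 animals with ", n_events,
           " events in session ", first_session, call. = FALSE)
    }
    m_icc <- t(vapply(keep, function(a) {
      head(s1$value[s1$animal_id == a], n_events)
    }, numeric(n_events)))
    icc <- icc3k(m_icc, alpha = alpha)

    anova <- NULL
    session_means <- session_sds <- NULL
    if (length(sessions) >= 2) {
      # per-animal session means over the first n_events events
      agg <- lapply(sessions, function(s) {
        ss <- sub[sub$session_id == s, ]
        ss <- ss[order(ss$animal_id, ss$event_index), ]
        sapply(split(ss$value, ss$animal_id),
               function(v) if (length(v) >= n_events) mean(head(v, n_events))
                           else NA_real_)
      })
      animals <- Reduce(intersect, lapply(agg, names))
      m <- sapply(seq_along(sessions), function(j) agg[[j]][animals])
      complete <- stats::complete.cases(m)
      if (any(!complete)) {
        warning("feature ", f, ": excluding animal(s) without complete ",
                "sessions: ", paste(animals[!complete], collapse = ", "),
                call. = FALSE)
      }
      m <- m[complete, , drop = FALSE]
      if (nrow(m) < 2) {
        stop("feature ", f, ": fewer than 2 animals with complete sessions",
             call. = FALSE)
      }
      anova <- rm_anova(m)
      session_means <- anova$session_means
      session_sds <- anova$session_sds
    } else {
      s1m <- rowMeans(m_icc)
      session_means <- mean(s1m)
      session_sds <- sd(s1m)
    }
    per_feature[[f]] <- list(
      icc = icc, anova = anova,
      session_means = session_means, session_sds = session_sds,
      n_animals = length(keep),
      significant = if (!is.null(anova)) anova$p < alpha else NA
    )
  }
  structure(list(features = per_feature, alpha = alpha, n_events = n_events,
                 sessions = sessions),
            class = "stuc_reliability")
}

#' @export
print.stuc_reliability <- function(x, ...) {
  cat(sprintf(
    "Serial cystometry reliability (%d features, %d session(s), %d events/session)\n",
    length(x$features), length(x$sessions), x$n_events))
  for (f in names(x$features)) {
    e <- x$features[[f]]
    line <- sprintf("  %-20s ICC(3,k) %.2f (%.2f, %.2f) [%s]", f,
                    e$icc$icc, e$icc$ci[1], e$icc$ci[2], e$icc$band)
    if (!is.null(e$anova)) {
      line <- paste0(line, sprintf("  ANOVA p = %.3f%s", e$anova$p,
                                   if (isTRUE(e$significant)) " *" else ""))
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' @export
summary.stuc_reliability <- function(object, ...) {
  cat("Within-session reliability (first session, ICC(3,k)):\n\n")
  cat(report_markdown(object), sep = "\n")
  invisible(object)
}

#' @export
coef.stuc_reliability <- function(object, ...) {
  t(vapply(object$features, function(e) {
    c(icc = e$icc$icc, ci_low = e$icc$ci[1], ci_high = e$icc$ci[2],
      anova_f = if (!is.null(e$anova)) e$anova$f else NA_real_,
      anova_p = if (!is.null(e$anova)) e$anova$p else NA_real_)
  }, numeric(5)))
}

#' Write a reliability report as JSON
#'
#' One object per feature: `icc`, `ci`, `band`, `session_means`,
#' `session_sds`, `anova_f`, `anova_p` (the last two `NULL` for
#' single-session tables).
#'
#' @param rel a [stuc_reliability()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
report_json <- function(rel, path) {
  out <- lapply(rel$features, function(e) {
    list(icc = e$icc$icc, ci = e$icc$ci, band = e$icc$band,
         n_animals = e$n_animals,
         session_means = as.numeric(e$session_means),
         session_sds = as.numeric(e$session_sds),
         anova_f = if (!is.null(e$anova)) e$anova$f else NULL,
         anova_p = if (!is.null(e$anova)) e$anova$p else NULL)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Render a reliability report as markdown tables
#'
#' Two tables mirroring the customary reporting layout: within-session
#' ICC(3,k) with 95% CI per feature, and per-session mean (SD) with the
#' repeated-measures ANOVA p-value per feature.
#'
#' @param rel a [stuc_reliability()] object.
#' @param path optional output file.
#' @return Character vector of markdown lines (invisibly if `path` given).
#' @export
report_markdown <- function(rel, path = NULL) {
  lines <- c("| Feature | ICC(3,k) (95% CI) | Band |",
             "|---|---|---|")
  for (f in names(rel$features)) {
    e <- rel$features[[f]]
    lines <- c(lines, sprintf("| %s | %.2f (%.2f, %.2f) | %s |", f,
                              e$icc$icc, e$icc$ci[1], e$icc$ci[2],
                              e$icc$band))
  }
  if (length(rel$sessions) >= 2) {
    hdr <- paste0("| Feature | ",
                  paste(sprintf("Session %s mean (SD)", rel$sessions),
                        collapse = " | "),
                  " | p value |")
    sep <- paste0("|", paste(rep("---", length(rel$sessions) + 2),
                             collapse = "|"), "|")
    lines <- c(lines, "", hdr, sep)
    for (f in names(rel$features)) {
      e <- rel$features[[f]]
      cells <- sprintf("%.3g (%.3g)", e$session_means, e$session_sds)
      lines <- c(lines, sprintf("| %s | %s | %.3f |", f,
                                paste(cells, collapse = " | "), e$anova$p))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
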