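#' Participant screening: correlation between target and reproduced distance
#'
#' Participants whose reproduced distances do not track the target distances
#' cannot have solved the task by reproducing distance (they typically press
#' after a characteristic duration instead). Per participant, a Pearson
#' correlation between target and reproduced distances is computed over all
#' their trials; the participant is excluded when the two-sided p-value
#' (t distribution, n - 2 df) is at or above `alpha_level`, when the
#' correlation is non-positive, or when the correlation is undefined
#' (constant responses).
#'
#' @param table a trial table.
#' @param alpha_level significance level of the screen (default 0.05).
#' @return list with `kept` (trial table restricted to retained
#'   participants) and `excluded` (data frame of participant id, reason,
#'   r and p for each exclusion).
#' @export
screen_participants <- function(table, alpha_level = 0.05) {
  ids <- unique(table$participant_id)
  rec <- lapply(ids, function(id) {
    d <- table[table$participant_id == id, ]
    stop_if(nrow(d) < 3, sprintf("participant %s has fewer than 3 trials", id))
    if (stats::sd(d$reproduced_distance) == 0 ||
        stats::sd(d$target_distance) == 0) {
      return(data.frame(participant_id = id, reason = "zero_variance",
                        r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(d$target_distance, d$reproduced_distance,
                          method = "pearson", alternative = "two.sided")
    r <- unname(ct$estimate); p <- ct$p.value
    reason <- if (p >= alpha_level) "non_significant_correlation"
              else if (r <= 0) "non_positive_correlation" else NA_character_
    data.frame(participant_id = id, reason = reason, r = r, p = p)
  })
  rec <- do.call(rbind, rec)
  excluded <- rec[!is.na(rec$reason), , drop = FALSE]
  rownames(excluded) <- NULL
  kept <- table[!(table$participant_id %in% excluded$participant_id), ,
                drop = FALSE]
  attr(kept, "config") <- attr(table, "config")
  class(kept) <- class(table)
  list(kept = kept, excluded = excluded)
}

#' Trial-level outlier removal
#'
#' Drops trials whose absolute error deviates more than two standard
#' deviations from the participant's overall mean absolute error, pooled
#' over both orientations and all directions. Applied once (not iterated),
#' after participant screening. Participants contributing fewer than two
#' trials are left untouched (their SD is undefined).
#'
#' @param table a screened trial table.
#' @return list with `trials` (cleaned table), `removed_fraction` and
#'   `n_removed`.
#' @export
remove_outlier_trials <- function(table) {
  keep <- rep(TRUE, nrow(table))
  for (id in unique(table$participant_id)) {
    idx <- which(table$participant_id == id)
    if (length(idx) < 2) next
    e <- table$abs_error[idx]
    m <- mean(e); s <- stats::sd(e)
    keep[idx] <- abs(e - m) <= 2 * s
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "config") <- attr(table, "config")
  class(out) <- class(table)
  list(trials = out,
       removed_fraction = mean(!keep),
       n_removed = sum(!keep))
}

#' Per-direction error pattern in a chosen reference frame
#'
#' Mean absolute error in each of the 12 direction bins for one body
#' orientation, with directions optionally relabelled into the body frame
#' (earth direction minus the backward pitch, wrapped onto the grid). For
#' the upright orientation the two frames coincide.
#'
#' @param table a cleaned trial table.
#' @param orientation `"upright"` or `"pitch30"`.
#' @param frame `"earth"` or `"body"`.
#' @param pitch_deg backward pitch of the pitched orientation (default 30).
#' @return an `error_pattern`: data frame `direction_deg`,
#'   `mean_abs_error`, `n` over the full 12-bin grid (empty bins have
#'   `n = 0` and `NA` mean), with `frame` and `orientation` attributes.
#' @export
error_pattern <- function(table, orientation, frame = c("earth", "body"),
                          pitch_deg = 30) {
  orientation <- match.arg(orientation, c("upright", "pitch30"))
  frame <- match.arg(frame)
  d <- table[table$orientation == orientation, , drop = FALSE]
  dir <- d$direction_deg
  if (frame == "body" && orientation == "pitch30")
    dir <- wrap_angle(dir - pitch_deg)
  grid <- direction_grid()
  stop_if(!all(dir %in% grid), "directions off the 30-degree grid")
  f <- factor(dir, levels = grid)
  mean_abs <- tapply(d$abs_error, f, mean)
  n <- tapply(d$abs_error, f, length)
  n[is.na(n)] <- 0
  structure(
    data.frame(direction_deg = grid,
               mean_abs_error = as.numeric(mean_abs),
               n = as.integer(n)),
    frame = frame, orientation = orientation,
    class = c("error_pattern", "data.frame"))
}

#' Full preprocessing: participant screen then trial outlier removal
#'
#' The order is part of the contract: participants are screened first, and
#' the outlier rule then uses only retained participants' trials.
#'
#' @inheritParams screen_participants
#' @return list with `trials`, `excluded_participants`, `removed_fraction`.
#' @export
preprocess_cohort <- function(table, alpha_level = 0.05) {
  scr <- screen_participants(table, alpha_level)
  cln <- remove_outlier_trials(scr$kept)
  list(trials = cln$trials,
       excluded_participants = scr$excluded,
       removed_fraction = cln$removed_fraction)
}
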