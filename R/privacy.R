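#' Five-factor bedroom privacy instrument
#'
#' Scores the architectural privacy of a shared bedroom on five factors —
#' occupancy, adjacency, transitional spaces, visibility, visual privacy —
#' each coded from the built environment, summing to a 0–11 total where a
#' higher total means more privacy.
#'
#' The factor codings:
#' \describe{
#'   \item{occupancy}{How many people share the bedroom? 5+ = 0; 4 = 1;
#'     3 = 2; 2 or fewer = 3.}
#'   \item{adjacency}{What type of space is the bedroom next to? public = 0;
#'     semi-public = 1; semi-private = 2; private = 3.}
#'   \item{transitional}{Number of transitional spaces between the bedroom
#'     and the common area: none = 0; one = 1; two = 2; three or more = 3.}
#'   \item{visibility}{Can residents see the common areas from the bedroom?
#'     Two published coding directions exist for this factor (the instrument
#'     text codes yes = 0, while the applied per-room scores code yes = 1);
#'     both are supported via `visibility_coding` and the default is the
#'     applied direction (`"applied"`, yes = 1).}
#'   \item{visual privacy}{Can residents' beds be seen from the common
#'     areas? yes = 0; no = 1.}
#' }
#'
#' @param n_occupants number of people sharing the bedroom (bed capacity).
#' @return integer factor score.
#' @export
#' @examples
#' score_occupancy(3) # 2
#' score_adjacency("semi_private") # 2
score_occupancy <- function(n_occupants) {
  n <- assert_count(n_occupants, "n_occupants", min = 1L)
  if (n >= 5L) 0L else if (n == 4L) 1L else if (n == 3L) 2L else 3L
}

#' @rdname score_occupancy
#' @param adjacency_class one of `"private"`, `"semi_private"`,
#'   `"semi_public"`, `"public"`.
#' @export
score_adjacency <- function(adjacency_class) {
  scores <- c(public = 0L, semi_public = 1L, semi_private = 2L, private = 3L)
  if (length(adjacency_class) != 1L || !adjacency_class %in% names(scores)) {
    stop_invalid("unknown adjacency_class: %s",
                 paste(adjacency_class, collapse = ","))
  }
  scores[[adjacency_class]]
}

#' @rdname score_occupancy
#' @param n_transitional number of transitional spaces between the bedroom
#'   and the common area.
#' @export
score_transitional <- function(n_transitional) {
  n <- assert_count(n_transitional, "n_transitional", min = 0L)
  min(n, 3L)
}

#' @rdname score_occupancy
#' @param sees_common logical: can residents see the common areas from the
#'   bedroom.
#' @param visibility_coding `"applied"` (sees common areas scores 1, the
#'   default) or `"instrument"` (sees common areas scores 0).
#' @export
score_visibility <- function(sees_common,
                             visibility_coding = c("applied", "instrument")) {
  visibility_coding <- match.arg(visibility_coding)
  if (length(sees_common) != 1L || is.na(sees_common) || !is.logical(sees_common)) {
    stop_invalid("sees_common must be TRUE or FALSE")
  }
  if (visibility_coding == "applied") as.integer(sees_common) else as.integer(!sees_common)
}

#' @rdname score_occupancy
#' @param beds_visible logical: can residents' beds be seen from the common
#'   areas.
#' @export
score_visual_privacy <- function(beds_visible) {
  if (length(beds_visible) != 1L || is.na(beds_visible) || !is.logical(beds_visible)) {
    stop_invalid("beds_visible must be TRUE or FALSE")
  }
  as.integer(!beds_visible)
}

#' Assess the privacy of one bedroom
#'
#' Applies the five scoring rules to a bedroom zone and returns the factor
#' scores and their 0–11 total.
#'
#' @param zone single-row bedroom zone record (a row of `facility$zones`),
#'   or a list with the same fields.
#' @param n_occupants number of people sharing the bedroom; defaults to the
#'   zone's declared bed capacity `n_beds`.
#' @inheritParams score_visibility
#' @return one-row data.frame of class `privacy_assessment` with columns
#'   `bedroom_zone`, `occupancy_score`, `adjacency_score`,
#'   `transitional_score`, `visibility_score`, `visual_privacy_score`,
#'   `total`.
#' @export
assess_bedroom <- function(zone, n_occupants = NULL,
                           visibility_coding = c("applied", "instrument")) {
  visibility_coding <- match.arg(visibility_coding)
  zone <- as.list(zone)
  if (!identical(zone$zone_class, "bedroom")) {
    stop_invalid("zone %s is not a bedroom", zone$zone_id %||% "?")
  }
  n_occupants <- n_occupants %||% zone$n_beds
  out <- data.frame(
    bedroom_zone = zone$zone_id,
    occupancy_score = score_occupancy(n_occupants),
    adjacency_score = score_adjacency(zone$adjacency_class),
    transitional_score = score_transitional(zone$n_transitional_to_common),
    visibility_score = score_visibility(zone$sees_common, visibility_coding),
    visual_privacy_score = score_visual_privacy(zone$beds_visible_from_common),
    stringsAsFactors = FALSE
  )
  out$total <- out$occupancy_score + out$adjacency_score +
    out$transitional_score + out$visibility_score + out$visual_privacy_score
  class(out) <- c("privacy_assessment", class(out))
  out
}

#' Assess every bedroom in a facility
#'
#' @param fac a [facility()].
#' @inheritParams score_visibility
#' @return data.frame with one row per bedroom zone (factor scores and
#'   total) plus the bedroom type of the room.
#' @export
assess_facility <- function(fac, visibility_coding = c("applied", "instrument")) {
  visibility_coding <- match.arg(visibility_coding)
  bz <- fac$zones[fac$zones$zone_class == "bedroom", , drop = FALSE]
  rows <- lapply(seq_len(nrow(bz)), function(i) {
    assess_bedroom(bz[i, ], visibility_coding = visibility_coding)
  })
  out <- do.call(rbind, rows)
  bt <- fac$residents$bedroom_type[match(out$bedroom_zone, fac$residents$bedroom_zone)]
  out$bedroom_type <- bt
  rownames(out) <- NULL
  out
}

#' Per-resident privacy predictors
#'
#' Broadcasts bedroom-level privacy scores to the residents living in each
#' bedroom, yielding the predictor block used by the association analysis.
#' Within-bedroom rows are identical by construction (the scores are
#' room-level properties), which the association layer documents as a
#' non-independence caveat.
#'
#' @inheritParams assess_facility
#' @return data.frame with one row per resident: `resident_id`, the five
#'   factor scores, and `total`.
#' @export
privacy_by_resident <- function(fac, visibility_coding = c("applied", "instrument")) {
  pa <- assess_facility(fac, visibility_coding = match.arg(visibility_coding))
  idx <- match(fac$residents$bedroom_zone, pa$bedroom_zone)
  out <- data.frame(
    resident_id = fac$residents$resident_id,
    occupancy_score = pa$occupancy_score[idx],
    adjacency_score = pa$adjacency_score[idx],
    transitional_score = pa$transitional_score[idx],
    visibility_score = pa$visibility_score[idx],
    visual_privacy_score = pa$visual_privacy_score[idx],
    total = pa$total[idx],
    stringsAsFactors = FALSE
  )
  out
}
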