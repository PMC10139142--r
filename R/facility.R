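#' Facility description: zones, bedrooms and residents
#'
#' A facility is the single source of truth for the built environment: its
#' zones (bedrooms, common areas, transitional spaces), the architectural
#' attributes of each bedroom that feed the privacy instrument, and the
#' resident roster mapping each tracked resident to a bedroom. No geometric
#' inference is performed; everything is declared in the description.
#'
#' @param zones data.frame with columns `zone_id`, `zone_class` (one of
#'   `"bedroom"`, `"common_area"`, `"transitional"`, `"other"`), and, for
#'   bedroom zones, `adjacency_class` (`"private"`, `"semi_private"`,
#'   `"semi_public"`, `"public"`), `n_transitional_to_common` (count),
#'   `sees_common` (logical: can residents see common areas from the room),
#'   `beds_visible_from_common` (logical), `n_beds` (bed capacity). An
#'   optional `neighbours` list-column names physically adjacent zones
#'   (used by the sensor cross-talk model).
#' @param residents data.frame with columns `resident_id`, `bedroom_zone`,
#'   `bedroom_type` (one of `"three_bed"`, `"four_bed_corridor"`,
#'   `"four_bed_common"`, `"five_bed"`) and optionally `sex`.
#' @return an object of class `facility`.
#' @seealso [read_facility()], [build_default_facility()], [assess_bedroom()]
#' @export
facility <- function(zones, residents) {
  zones <- as.data.frame(zones, stringsAsFactors = FALSE)
  residents <- as.data.frame(residents, stringsAsFactors = FALSE)
  obj <- structure(list(zones = zones, residents = residents),
                   class = "facility")
  validate_facility(obj)
}

ZONE_CLASSES <- c("bedroom", "common_area", "transitional", "other")
ADJACENCY_CLASSES <- c("private", "semi_private", "semi_public", "public")
BEDROOM_TYPES <- c("three_bed", "four_bed_corridor", "four_bed_common", "five_bed")

#' @rdname facility
#' @param x object to validate.
#' @export
validate_facility <- function(x) {
  z <- x$zones; r <- x$residents
  need_z <- c("zone_id", "zone_class")
  if (!all(need_z %in% names(z))) {
    stop_config("zones must have columns %s", paste(need_z, collapse = ", "))
  }
  if (anyDuplicated(z$zone_id)) {
    stop_config("duplicate zone_id: %s",
                paste(unique(z$zone_id[duplicated(z$zone_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(z$zone_class), ZONE_CLASSES)
  if (length(bad)) stop_config("unknown zone_class: %s", paste(bad, collapse = ", "))
  bz <- z[z$zone_class == "bedroom", , drop = FALSE]
  if (nrow(bz)) {
    need_b <- c("adjacency_class", "n_transitional_to_common",
                "sees_common", "beds_visible_from_common")
    miss <- setdiff(need_b, names(z))
    if (length(miss)) stop_config("bedroom zones need columns %s",
                                  paste(miss, collapse = ", "))
    bad <- setdiff(unique(bz$adjacency_class), ADJACENCY_CLASSES)
    if (length(bad)) stop_config("unknown adjacency_class: %s",
                                 paste(bad, collapse = ", "))
  }
  need_r <- c("resident_id", "bedroom_zone", "bedroom_type")
  if (!all(need_r %in% names(r))) {
    stop_config("residents must have columns %s", paste(need_r, collapse = ", "))
  }
  if (anyDuplicated(r$resident_id)) stop_config("duplicate resident_id")
  orphan <- setdiff(r$bedroom_zone, z$zone_id[z$zone_class == "bedroom"])
  if (length(orphan)) {
    stop_config("bedroom_zone not a bedroom zone: %s", paste(orphan, collapse = ", "))
  }
  bad <- setdiff(unique(r$bedroom_type), BEDROOM_TYPES)
  if (length(bad)) stop_config("unknown bedroom_type: %s", paste(bad, collapse = ", "))
  x
}

#' @export
print.facility <- function(x, ...) {
  cat(sprintf("<facility> %d zones (%d bedrooms), %d residents\n",
              nrow(x$zones), sum(x$zones$zone_class == "bedroom"),
              nrow(x$residents)))
  tab <- table(x$residents$bedroom_type)
  for (nm in names(tab)) cat(sprintf("  %-18s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Roommates of a resident
#'
#' @param fac a [facility()].
#' @param resident_id resident identifier.
#' @return character vector of resident ids sharing the bedroom, excluding
#'   the resident itself.
#' @export
roommates <- function(fac, resident_id) {
  r <- fac$residents
  i <- match(resident_id, r$resident_id)
  if (is.na(i)) stop_invalid("unknown resident: %s", resident_id)
  setdiff(r$resident_id[r$bedroom_zone == r$bedroom_zone[i]], resident_id)
}

#' Roommate indicator matrix for the whole roster
#' @param fac a [facility()].
#' @return logical matrix with resident ids as dimnames; TRUE where the two
#'   residents share a bedroom (diagonal FALSE).
#' @export
roommate_matrix <- function(fac) {
  r <- fac$residents
  m <- outer(r$bedroom_zone, r$bedroom_zone, "==")
  diag(m) <- FALSE
  dimnames(m) <- list(r$resident_id, r$resident_id)
  m
}

zone_class_of <- function(fac, zone_ids) {
  fac$zones$zone_class[match(zone_ids, fac$zones$zone_id)]
}

#' Read / write a facility description
#'
#' The on-disk format is YAML (or JSON) with two sections, `zones:` and
#' `residents:`, each a list of records mirroring the [facility()] columns.
#' The description is validated on load.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return [read_facility()] returns a `facility`; [write_facility()]
#'   returns `path` invisibly.
#' @export
read_facility <- function(path) {
  if (!file.exists(path)) stop_config("facility file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!all(c("zones", "residents") %in% names(raw))) {
    stop_config("facility file needs top-level `zones:` and `residents:` sections")
  }
  zl <- raw$zones
  zones <- data.frame(
    zone_id = vapply(zl, function(z) as.character(z$zone_id), ""),
    zone_class = vapply(zl, function(z) as.character(z$zone_class), ""),
    adjacency_class = vapply(zl, function(z) as.character(z$adjacency_class %||% NA_character_), ""),
    n_transitional_to_common = vapply(zl, function(z) as.numeric(z$n_transitional_to_common %||% NA_real_), 0),
    sees_common = vapply(zl, function(z) as.logical(z$sees_common %||% NA), NA),
    beds_visible_from_common = vapply(zl, function(z) as.logical(z$beds_visible_from_common %||% NA), NA),
    n_beds = vapply(zl, function(z) as.numeric(z$n_beds %||% NA_real_), 0),
    stringsAsFactors = FALSE
  )
  zones$neighbours <- lapply(zl, function(z) as.character(unlist(z$neighbours)))
  rl <- raw$residents
  residents <- data.frame(
    resident_id = vapply(rl, function(r) as.character(r$resident_id), ""),
    bedroom_zone = vapply(rl, function(r) as.character(r$bedroom_zone), ""),
    bedroom_type = vapply(rl, function(r) as.character(r$bedroom_type), ""),
    sex = vapply(rl, function(r) as.character(r$sex %||% NA_character_), ""),
    stringsAsFactors = FALSE
  )
  facility(zones, residents)
}

#' @rdname read_facility
#' @param fac a [facility()].
#' @export
write_facility <- function(fac, path) {
  zl <- lapply(seq_len(nrow(fac$zones)), function(i) {
    z <- as.list(fac$zones[i, setdiff(names(fac$zones), "neighbours")])
    z <- z[!vapply(z, function(v) is.na(v) || (is.character(v) && v == "NA"), TRUE)]
    if (!is.null(fac$zones$neighbours)) z$neighbours <- fac$zones$neighbours[[i]]
    z
  })
  rl <- lapply(seq_len(nrow(fac$residents)), function(i) {
    r <- as.list(fac$residents[i, ])
    r[!vapply(r, function(v) is.na(v) || identical(v, "NA"), TRUE)]
  })
  yaml::write_yaml(list(zones = zl, residents = rl), path)
  invisible(path)
}
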