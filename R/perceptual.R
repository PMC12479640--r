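# Perceptual rating schema for cervical auscultation: a closed inventory
# of pre-, during- and post-swallow sound parameters rated
# yes/no/cannot_be_determined over a 2-minute feeding observation, with
# a presence-plus-consistency rule for during-swallow sounds, two-rater
# consensus, and a rule-based coordinated/uncoordinated classifier.

#' Breath-sound parameters (rated pre- and post-swallow)
#' @export
BREATH_SOUND_PARAMETERS <- c(
  "normal_breathing", "wet_breathing", "rattly_chest", "grunting",
  "crackles", "stridor", "wheeze", "throat_clearing", "coughing"
)

#' During-swallow sound parameters
#'
#' `IDS`/`BTS`/`FDS`/`GRS` are the initial discrete sound, bolus transit
#' sound, final discrete sound and glottal release sound of the canonical
#' swallow-sound sequence.
#' @export
SWALLOW_SOUND_PARAMETERS <- c(
  "crisp_clear", "quick", "loud", "IDS", "BTS", "FDS", "GRS"
)

# Adventitious post-swallow breath sounds entering the uncoordinated rule
ADVENTITIOUS_SOUNDS <- c(
  "wet_breathing", "rattly_chest", "coughing", "wheeze",
  "crackles", "throat_clearing", "stridor"
)

RATING_VALUES <- c("yes", "no", "cannot_be_determined")

#' The perceptual parameter inventory
#'
#' @return `data.frame` with columns `phase` (`pre`, `during`, `post`)
#'   and `parameter`; the inventory is closed — ratings for unknown
#'   parameters are rejected.
#' @export
perceptual_inventory <- function() {
  data.frame(
    phase = c(
      rep("pre", length(BREATH_SOUND_PARAMETERS)),
      rep("during", length(SWALLOW_SOUND_PARAMETERS)),
      rep("post", length(BREATH_SOUND_PARAMETERS))
    ),
    parameter = c(
      BREATH_SOUND_PARAMETERS, SWALLOW_SOUND_PARAMETERS, BREATH_SOUND_PARAMETERS
    ),
    stringsAsFactors = FALSE
  )
}

validate_ratings <- function(ratings) {
  required <- c("phase", "parameter", "value")
  missing <- setdiff(required, names(ratings))
  if (length(missing)) {
    sca_error(sprintf("ratings missing column(s): %s", paste(missing, collapse = ", ")),
              "swallowCA_bad_table")
  }
  if (!"consistent" %in% names(ratings)) ratings$consistent <- NA_character_
  ratings$consistent[ratings$consistent %in% c("", NA)] <- NA_character_

  inv <- perceptual_inventory()
  key <- paste(ratings$phase, ratings$parameter)
  bad <- !key %in% paste(inv$phase, inv$parameter)
  if (any(bad)) {
    sca_error(
      sprintf("unknown phase/parameter: %s", paste(unique(key[bad]), collapse = "; ")),
      "swallowCA_unknown_parameter"
    )
  }
  if (anyDuplicated(key)) {
    sca_error("duplicated phase/parameter rating", "swallowCA_bad_table")
  }
  if (!all(ratings$value %in% RATING_VALUES)) {
    sca_error("rating values must be yes/no/cannot_be_determined", "swallowCA_bad_table")
  }
  has_flag <- !is.na(ratings$consistent)
  flag_ok <- ratings$phase == "during" & ratings$value == "yes"
  if (any(has_flag & !flag_ok)) {
    sca_error("consistency flags are only valid for during-swallow parameters rated yes",
              "swallowCA_bad_table")
  }
  if (any(has_flag & !ratings$consistent %in% c("yes", "no"))) {
    sca_error("consistency flag must be yes or no", "swallowCA_bad_table")
  }
  ratings[c("phase", "parameter", "value", "consistent")]
}

#' Construct a perceptual profile
#'
#' One rater's (or the consensus) ratings for one neonate over the full
#' parameter inventory. The coordination class is always derived from the
#' ratings via [classify_coordination()], never stored independently.
#'
#' @param neonate_id,rater_id identifiers (`rater_id = "consensus"` for
#'   consensus profiles).
#' @param ratings `data.frame` with columns `phase`, `parameter`, `value`
#'   and optionally `consistent`; must cover the complete inventory.
#' @return object of class `perceptual_profile`.
#' @export
perceptual_profile <- function(neonate_id, rater_id, ratings) {
  ratings <- validate_ratings(ratings)
  inv <- perceptual_inventory()
  missing <- setdiff(paste(inv$phase, inv$parameter),
                     paste(ratings$phase, ratings$parameter))
  if (length(missing)) {
    sca_error(sprintf("incomplete rating set; missing: %s", paste(missing, collapse = "; ")),
              "swallowCA_bad_table")
  }
  cls <- classify_coordination(ratings)
  structure(
    list(
      neonate_id = as.character(neonate_id),
      rater_id = as.character(rater_id),
      ratings = ratings,
      coordination = cls
    ),
    class = "perceptual_profile"
  )
}

#' @export
print.perceptual_profile <- function(x, ...) {
  cat(sprintf("<perceptual_profile> neonate %s, rater %s: %s swallow\n",
              x$neonate_id, x$rater_id, x$coordination))
  invisible(x)
}

get_rating <- function(ratings, phase, parameter) {
  v <- ratings$value[ratings$phase == phase & ratings$parameter == parameter]
  if (length(v) != 1L) {
    sca_error(sprintf("missing rating for %s/%s", phase, parameter),
              "swallowCA_bad_table")
  }
  v
}

#' Presence and consistency of a during-swallow parameter
#'
#' A parameter is present if it was demonstrated on at least one swallow
#' of the observation. A present sound is consistent when it occurred in
#' strictly more than 80% of all identified swallows (the 80% boundary
#' itself is not consistent).
#'
#' @param present logical vector, one element per identified swallow.
#' @return list with `value` (`"yes"`/`"no"`) and `consistent`
#'   (`"yes"`/`"no"` when present, `NA` otherwise).
#' @export
presence_from_swallows <- function(present) {
  if (length(present) < 1L) {
    sca_error("presence vector must cover at least one swallow", "swallowCA_bad_parameter")
  }
  present <- as.logical(present)
  if (anyNA(present)) sca_error("presence vector must not contain NA", "swallowCA_bad_parameter")
  if (!any(present)) return(list(value = "no", consistent = NA_character_))
  list(
    value = "yes",
    consistent = if (mean(present) > 0.80) "yes" else "no"
  )
}

#' Classify a swallow-sound profile as coordinated or uncoordinated
#'
#' A coordinated swallow requires a bolus transit sound (BTS) together
#' with either normal breathing post-swallow or no change between the
#' pre- and post-swallow breath-sound profiles (equality of the nine
#' breath-sound ratings). An uncoordinated swallow is a BTS with absent
#' normal breathing post-swallow, or a glottal release sound (GRS) plus
#' at least one adventitious post-swallow sound (wet breathing, rattly
#' chest, cough, wheeze, crackles, throat clearing, stridor) — two
#' independent sufficient conditions. When both rules fire,
#' uncoordinated takes precedence (the clinically conservative call: a
#' file can show normal breathing on one swallow and adventitious sounds
#' on another).
#'
#' @param ratings a rating `data.frame` (see [perceptual_profile()]) or a
#'   `perceptual_profile`.
#' @return `"coordinated"`, `"uncoordinated"` or `"undetermined"` (the
#'   latter carries a `reason` attribute).
#' @export
classify_coordination <- function(ratings) {
  if (inherits(ratings, "perceptual_profile")) ratings <- ratings$ratings
  ratings <- validate_ratings(ratings)

  bts <- get_rating(ratings, "during", "BTS")
  if (bts == "cannot_be_determined") {
    return(structure("undetermined", reason = "BTS rating cannot be determined"))
  }
  grs <- get_rating(ratings, "during", "GRS")
  post_normal <- get_rating(ratings, "post", "normal_breathing")
  post_advent <- vapply(ADVENTITIOUS_SOUNDS, function(p) get_rating(ratings, "post", p),
                        character(1))

  uncoordinated <-
    (bts == "yes" && post_normal == "no") ||
    (grs == "yes" && any(post_advent == "yes"))
  if (uncoordinated) return("uncoordinated")

  pre_vec <- vapply(BREATH_SOUND_PARAMETERS, function(p) get_rating(ratings, "pre", p),
                    character(1))
  post_vec <- vapply(BREATH_SOUND_PARAMETERS, function(p) get_rating(ratings, "post", p),
                     character(1))
  no_change <- all(pre_vec != "cannot_be_determined") &&
    all(post_vec != "cannot_be_determined") && all(pre_vec == post_vec)

  if (bts == "yes" && (post_normal == "yes" || no_change)) {
    return("coordinated")
  }
  reason <- if (bts == "no") {
    "no bolus transit sound present"
  } else {
    "required post-swallow ratings cannot be determined"
  }
  structure("undetermined", reason = reason)
}

#' Merge two raters' profiles into a consensus profile
#'
#' Parameters on which the raters agree (value and, for during-swallow
#' sounds, consistency flag) pass through unchanged. Every disagreement
#' must have an entry in `resolutions`; an unresolved disagreement is an
#' error naming the parameters still needing discussion.
#'
#' @param rater_a,rater_b [perceptual_profile()]s for the same neonate.
#' @param resolutions named list, `"phase:parameter"` to a list with
#'   `value` and optionally `consistent`.
#' @return a consensus [perceptual_profile()] (`rater_id = "consensus"`).
#' @export
consensus_profile <- function(rater_a, rater_b, resolutions = list()) {
  stopifnot(inherits(rater_a, "perceptual_profile"),
            inherits(rater_b, "perceptual_profile"))
  if (!identical(rater_a$neonate_id, rater_b$neonate_id)) {
    sca_error("consensus requires profiles of the same neonate", "swallowCA_bad_parameter")
  }
  a <- rater_a$ratings
  key <- paste(a$phase, a$parameter, sep = ":")
  b <- rater_b$ratings[match(key, paste(rater_b$ratings$phase, rater_b$ratings$parameter,
                                        sep = ":")), ]

  same <- a$value == b$value &
    (is.na(a$consistent) & is.na(b$consistent) |
       (!is.na(a$consistent) & !is.na(b$consistent) & a$consistent == b$consistent))

  out <- a
  unresolved <- character(0)
  for (i in which(!same)) {
    res <- resolutions[[key[i]]]
    if (is.null(res)) {
      unresolved <- c(unresolved, key[i])
    } else {
      out$value[i] <- res$value
      out$consistent[i] <- res$consistent %||% NA_character_
    }
  }
  if (length(unresolved)) {
    sca_error(
      sprintf("unresolved rating disagreement for: %s", paste(unresolved, collapse = ", ")),
      "swallowCA_unresolved_disagreement"
    )
  }
  perceptual_profile(rater_a$neonate_id, "consensus", out)
}

presence_percent <- function(n_present, n_rateable) {
  ifelse(n_rateable > 0, round_half_up(100 * n_present / n_rateable, 1), NA_real_)
}

#' Cohort presence table
#'
#' For each parameter, the number of neonates whose consensus rating is
#' `yes`, the available-case denominator (`cannot_be_determined` ratings
#' excluded), and the percentage rounded half-up to one decimal. With
#' `include_coordination = TRUE`, coordinated/uncoordinated rows derived
#' by [classify_coordination()] are appended (denominator = profiles with
#' a determined class).
#'
#' @param profiles list of consensus [perceptual_profile()]s.
#' @param include_coordination append coordination-class rows.
#' @return `data.frame` with `phase, parameter, n_present, n_rateable,
#'   percent`; row order follows the inventory, independent of profile
#'   order.
#' @export
cohort_presence_table <- function(profiles, include_coordination = TRUE) {
  if (!length(profiles)) sca_error("need at least one profile", "swallowCA_bad_parameter")
  inv <- perceptual_inventory()
  vals <- vapply(profiles, function(p) {
    key <- paste(p$ratings$phase, p$ratings$parameter)
    p$ratings$value[match(paste(inv$phase, inv$parameter), key)]
  }, character(nrow(inv)))
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1)

  n_present <- rowSums(vals == "yes")
  n_rateable <- rowSums(vals != "cannot_be_determined")
  out <- data.frame(
    phase = inv$phase, parameter = inv$parameter,
    n_present = n_present, n_rateable = n_rateable,
    percent = presence_percent(n_present, n_rateable),
    stringsAsFactors = FALSE, row.names = NULL
  )

  if (include_coordination) {
    cls <- vapply(profiles, function(p) as.character(p$coordination), character(1))
    n_det <- sum(cls != "undetermined")
    coord <- data.frame(
      phase = "coordination",
      parameter = c("coordinated", "uncoordinated"),
      n_present = c(sum(cls == "coordinated"), sum(cls == "uncoordinated")),
      n_rateable = n_det,
      stringsAsFactors = FALSE
    )
    coord$percent <- presence_percent(coord$n_present, coord$n_rateable)
    out <- rbind(out, coord)
  }
  out
}

#' Read a long-format ratings table
#'
#' CSV with header `neonate_id,rater_id,phase,parameter,value,consistent`
#' (the `consistent` column may be absent or empty).
#'
#' @param path CSV path.
#' @return validated `data.frame`.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) {
    sca_error(sprintf("ratings file not found: %s", path), "swallowCA_io_error")
  }
  r <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", na.strings = c("NA", ""))
  required <- c("neonate_id", "rater_id", "phase", "parameter", "value")
  missing <- setdiff(required, names(r))
  if (length(missing)) {
    sca_error(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")),
              "swallowCA_bad_table")
  }
  if (!"consistent" %in% names(r)) r$consistent <- NA_character_
  r
}

#' Write a long-format ratings table
#' @param ratings ratings `data.frame` (long format).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Build perceptual profiles from a long ratings table
#'
#' @param ratings long `data.frame` as from [read_ratings()].
#' @return named list of [perceptual_profile()]s, one per
#'   (neonate, rater) pair, names `"neonate_id/rater_id"`.
#' @export
profiles_from_ratings <- function(ratings) {
  keys <- unique(ratings[c("neonate_id", "rater_id")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- ratings[ratings$neonate_id == keys$neonate_id[i] &
                     ratings$rater_id == keys$rater_id[i], ]
    perceptual_profile(keys$neonate_id[i], keys$rater_id[i],
                       sub[c("phase", "parameter", "value", "consistent")])
  })
  names(out) <- paste(keys$neonate_id, keys$rater_id, sep = "/")
  out
}

#' Flatten perceptual profiles to a long ratings table
#' @param profiles list of [perceptual_profile()]s.
#' @return long `data.frame` (read back by [profiles_from_ratings()]).
#' @export
ratings_from_profiles <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    cbind(
      data.frame(neonate_id = p$neonate_id, rater_id = p$rater_id,
                 stringsAsFactors = FALSE),
      p$ratings
    )
  }))
}
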