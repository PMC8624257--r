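# Posture archetype catalog and posture groups.
#
# Each archetype carries an 8-channel relative muscle-activation profile
# (max-normalized to 1 for active postures) around the forearm ring, with
# channel 1 at the reference electrode position (anterior forearm, around
# the flexor carpi radialis). Profiles are hand-crafted fixtures: postures
# that share a function (the pinch triplet, the two grasps, the two
# thumb/index signs) are given highly correlated profiles, functionally
# distinct postures weakly or negatively correlated ones.

.POSTURE_PROFILES <- list(
  rest              = c(0.010, 0.004, 0.008, 0.002, 0.010, 0.006, 0.002, 0.008),
  cylindrical_grasp = c(1.00, 0.80, 0.50, 0.30, 0.20, 0.30, 0.50, 0.70),
  spherical_grasp   = c(1.00, 0.75, 0.55, 0.35, 0.20, 0.25, 0.45, 0.75),
  palmar_pinch      = c(0.30, 1.00, 0.70, 0.20, 0.10, 0.10, 0.20, 0.30),
  tip_pinch         = c(0.35, 1.00, 0.65, 0.25, 0.10, 0.15, 0.15, 0.30),
  lateral_pinch     = c(0.30, 0.90, 1.00, 0.30, 0.15, 0.10, 0.20, 0.25),
  thumb_up          = c(0.20, 0.30, 0.20, 1.00, 0.60, 0.30, 0.20, 0.10),
  scissor_sign      = c(0.25, 0.30, 0.25, 1.00, 0.70, 0.35, 0.15, 0.10),
  spread            = c(0.10, 0.20, 0.30, 0.30, 0.60, 1.00, 0.80, 0.30),
  finger_pointing   = c(0.20, 0.40, 0.20, 0.30, 1.00, 0.50, 0.20, 0.10),
  v_sign            = c(0.15, 0.30, 0.40, 0.20, 0.80, 1.00, 0.40, 0.20),
  ok_sign           = c(0.50, 0.60, 1.00, 0.40, 0.30, 0.20, 0.30, 0.40)
)

.SIMILARITY_PARENT <- c(
  tip_pinch = "palmar_pinch", lateral_pinch = "palmar_pinch",
  spherical_grasp = "cylindrical_grasp", scissor_sign = "thumb_up"
)

#' The 12 hand-posture identifiers
#'
#' @return character vector of the 12 posture ids, rest first.
#' @export
posture_ids <- function() names(.POSTURE_PROFILES)

#' Construct a posture archetype
#'
#' @param posture_id one of [posture_ids()].
#' @param activation_profile 8 non-negative channel weights; for active
#'   postures the maximum must be 1, for rest all entries must be small
#'   (at most 0.05).
#' @param similarity_parent optional posture id whose profile this one
#'   perturbs (same-function postures).
#' @return a `posture_archetype` object.
#' @export
posture_archetype <- function(posture_id, activation_profile,
                              similarity_parent = NULL) {
  if (length(activation_profile) != 8L)
    stopf("activation_profile must have exactly 8 entries, got %d",
          length(activation_profile))
  if (any(activation_profile < 0))
    stopf("activation_profile entries must be non-negative")
  if (identical(posture_id, "rest")) {
    if (any(activation_profile > 0.05))
      stopf("rest archetype entries must all be <= 0.05")
  } else if (abs(max(activation_profile) - 1) > 1e-12) {
    stopf("active archetype '%s' must be max-normalized to 1", posture_id)
  }
  structure(
    list(posture_id = posture_id,
         activation_profile = as.numeric(activation_profile),
         similarity_parent = similarity_parent),
    class = "posture_archetype"
  )
}

#' Default catalog of the 12 posture archetypes
#'
#' Returns the frozen activation-profile fixtures for the 12 postures.
#' Same-function postures (palmar/tip/lateral pinch, cylindrical/spherical
#' grasp, scissor-sign/thumb-up) have pairwise profile Pearson correlation
#' of at least 0.8; functionally distinct postures correlate weakly.
#'
#' @return named list of [posture_archetype] objects.
#' @export
default_archetype_catalog <- function() {
  lapply(stats::setNames(nm = posture_ids()), function(id) {
    parent <- if (id %in% names(.SIMILARITY_PARENT)) .SIMILARITY_PARENT[[id]]
    posture_archetype(id, .POSTURE_PROFILES[[id]], parent)
  })
}

#' Posture groups G1-G7
#'
#' The seven posture groups used in the group-comparison experiments:
#' G1 is the six-core set; G2-G5 add one posture each (finger pointing,
#' tip pinch, spherical grasp, scissor-sign); G6 is an alternative
#' seven-posture set chosen for distinct muscle activation; G7 is all 12.
#'
#' @return named list `G1`..`G7` of posture-id vectors.
#' @export
posture_groups <- function() {
  g1 <- c("rest", "cylindrical_grasp", "palmar_pinch", "thumb_up",
          "lateral_pinch", "spread")
  list(
    G1 = g1,
    G2 = c(g1, "finger_pointing"),
    G3 = c(g1, "tip_pinch"),
    G4 = c(g1, "spherical_grasp"),
    G5 = c(g1, "scissor_sign"),
    G6 = c("rest", "cylindrical_grasp", "palmar_pinch", "v_sign",
           "finger_pointing", "thumb_up", "lateral_pinch"),
    G7 = posture_ids()
  )
}

#' Resolve a posture group label to posture ids
#'
#' @param group a group label `"G1"`..`"G7"`, `"all"`, or a character
#'   vector of posture ids (returned as-is after validation).
#' @return character vector of posture ids.
#' @export
group_postures <- function(group) {
  if (length(group) == 1L && group %in% names(posture_groups()))
    return(posture_groups()[[group]])
  if (length(group) == 1L && identical(group, "all")) return(posture_ids())
  unknown <- setdiff(group, posture_ids())
  if (length(unknown))
    stopf("unknown posture id(s): %s", paste(unknown, collapse = ", "))
  group
}
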