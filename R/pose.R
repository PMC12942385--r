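#' Occluder pose validity engine
#'
#' The 3D-printed occluder carries four fiducial markers: id 1 (base plate,
#' left-eye test: covers the right eye), id 2 (base plate, right-eye test:
#' covers the left eye), id 3 (pinhole flap for the left eye) and id 4
#' (pinhole flap for the right eye).  A pose observation is the set of marker
#' ids detected in a frame plus the iris landmark positions; classification
#' yields one of `Left`, `Right`, `Left_ph`, `Right_ph`, `Invalid`, where the
#' label names the eye under test.
#'
#' @name pose_engine
NULL

POSE_LABELS <- c("Left", "Right", "Left_ph", "Right_ph", "Invalid")
LEFT_FAMILY <- c(1L, 3L)
RIGHT_FAMILY <- c(2L, 4L)

#' Construct a pose observation
#'
#' @param marker_ids Integer vector of detected marker ids (subset of 1..4).
#' @param marker_boxes Named list mapping id to a 4x2 matrix of corner points
#'   (image pixels, origin top-left, x right / y down).
#' @param iris_left,iris_right Length-2 numeric iris centres, or `NULL` when
#'   the landmark is hidden.
#' @param face_box Optional 4x2 matrix; `NULL` means no face was detected.
#' @param frame_index Integer frame counter.
#' @return An object of class `pose_observation`.
#' @export
pose_observation <- function(marker_ids = integer(), marker_boxes = list(),
                             iris_left = NULL, iris_right = NULL,
                             face_box = NULL, frame_index = 0L) {
  marker_ids <- sort(unique(as.integer(marker_ids)))
  if (length(marker_ids) && (any(marker_ids < 1L) || any(marker_ids > 4L)))
    stop_domain("marker ids must lie in 1..4")
  have <- as.integer(names(marker_boxes) %||% character())
  if (!all(marker_ids %in% have))
    stop_domain("every detected marker id needs a bounding box")
  structure(
    list(marker_ids = marker_ids, marker_boxes = marker_boxes,
         iris_left = iris_left, iris_right = iris_right,
         face_box = face_box, frame_index = as.integer(frame_index)),
    class = "pose_observation")
}

#' Classify an occluder pose from the detected marker-id set
#'
#' Pure function of the id set: `{1}` or `{3}` -> `Left`; `{2}` or `{4}` ->
#' `Right`; `{1,3}` -> `Left_ph`; `{2,4}` -> `Right_ph`; the empty set or any
#' mix of left-family (1, 3) and right-family (2, 4) ids -> `Invalid`.
#'
#' @param marker_ids Integer vector, subset of 1..4.
#' @return A pose label string.
#' @examples
#' classify_markers(c(1, 3))  # "Left_ph"
#' classify_markers(integer()) # "Invalid"
#' @export
classify_markers <- function(marker_ids) {
  ids <- sort(unique(as.integer(marker_ids)))
  if (length(ids) && (any(ids < 1L) || any(ids > 4L)))
    stop_domain("marker ids must lie in 1..4")
  left <- any(ids %in% LEFT_FAMILY)
  right <- any(ids %in% RIGHT_FAMILY)
  if (!length(ids) || (left && right)) return("Invalid")
  if (left) {
    if (setequal(ids, c(1L, 3L))) "Left_ph" else "Left"
  } else {
    if (setequal(ids, c(2L, 4L))) "Right_ph" else "Right"
  }
}

point_in_box <- function(pt, box, margin = 0) {
  xr <- range(box[, 1]); yr <- range(box[, 2])
  if (margin > 0) {
    d <- sqrt(diff(xr)^2 + diff(yr)^2) * margin
    xr <- xr + c(-d, d); yr <- yr + c(-d, d)
  }
  pt[1] >= xr[1] && pt[1] <= xr[2] && pt[2] >= yr[1] && pt[2] <= yr[2]
}

# Region the occluder body occupies: boxes of base-plate markers (1/2) when
# present, otherwise every available marker box (e.g. a lone pinhole flap).
occluder_region <- function(obs) {
  ids <- obs$marker_ids
  base <- ids[ids %in% c(1L, 2L)]
  use <- if (length(base)) base else ids
  boxes <- obs$marker_boxes[as.character(use)]
  do.call(rbind, boxes)
}

#' Check that the iris landmarks are consistent with a candidate pose
#'
#' The covered eye (the one *not* under test) must fall inside the occluder
#' region inflated by `margin`; a missing covered-eye landmark counts as
#' covered, since full occlusion hides it.  The tested eye's iris must lie
#' outside the region (and must be visible).
#'
#' @param obs A [pose_observation()].
#' @param candidate Candidate pose label, not `"Invalid"`.
#' @param margin Region inflation as a fraction of the box diagonal
#'   (default 0.10).
#' @return `TRUE`/`FALSE`; on `FALSE` the attribute `"reason"` explains why
#'   (`"NO_FACE"`, `"COVERED_IRIS_VISIBLE"`, `"TESTED_IRIS_HIDDEN"`,
#'   `"TESTED_IRIS_COVERED"`).
#' @export
iris_within_region <- function(obs, candidate, margin = 0.10) {
  stopifnot(candidate %in% setdiff(POSE_LABELS, "Invalid"))
  if (is.null(obs$face_box))
    return(structure(FALSE, reason = "NO_FACE"))
  tested_left <- candidate %in% c("Left", "Left_ph")
  tested <- if (tested_left) obs$iris_left else obs$iris_right
  covered <- if (tested_left) obs$iris_right else obs$iris_left
  region <- occluder_region(obs)
  if (is.null(region)) return(structure(FALSE, reason = "NO_FACE"))
  covered_ok <- is.null(covered) || point_in_box(covered, region, margin)
  if (!covered_ok) return(structure(FALSE, reason = "COVERED_IRIS_VISIBLE"))
  if (is.null(tested)) return(structure(FALSE, reason = "TESTED_IRIS_HIDDEN"))
  if (point_in_box(tested, region, margin))
    return(structure(FALSE, reason = "TESTED_IRIS_COVERED"))
  TRUE
}

#' Classify a full pose observation
#'
#' Marker-set classification demoted to `Invalid` when the iris-region check
#' fails; reproduces the nine-row golden pose table used for validation.
#'
#' @param obs A [pose_observation()].
#' @param margin Passed to [iris_within_region()].
#' @return An object of class `pose_classification`: list with `label`,
#'   `iris_check_passed`, `source_ids` and optional `reason`.
#' @export
classify_pose <- function(obs, margin = 0.10) {
  stopifnot(inherits(obs, "pose_observation"))
  label <- classify_markers(obs$marker_ids)
  iris_ok <- TRUE
  reason <- NULL
  if (label != "Invalid") {
    chk <- iris_within_region(obs, label, margin)
    iris_ok <- isTRUE(as.logical(chk))
    if (!iris_ok) {
      reason <- attr(chk, "reason")
      label <- "Invalid"
    }
  }
  structure(list(label = label, iris_check_passed = iris_ok,
                 source_ids = obs$marker_ids, reason = reason),
            class = "pose_classification")
}

#' @export
format.pose_classification <- function(x, ...) {
  paste0(x$label, " [ids ", paste(x$source_ids, collapse = ","), "]")
}

#' @export
print.pose_classification <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Debounce a frame-level pose stream into stable pose events
#'
#' A valid label is emitted only once it has been seen on `k` consecutive
#' frames; any `Invalid` frame is emitted immediately (fail fast) and resets
#' the run, so `Invalid` is absorbing until `k` consecutive identical valid
#' labels re-establish a pose.
#'
#' @param stream List of `pose_classification` objects, or a character vector
#'   of labels.
#' @param k Required run length (default 5 frames).
#' @return A data.frame with columns `frame` (1-based index into the stream)
#'   and `label`, one row per emitted event.
#' @export
debounce <- function(stream, k = 5L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_domain("`k` must be >= 1")
  labels <- if (is.character(stream)) stream
            else vapply(stream, `[[`, character(1), "label")
  out_frame <- integer(); out_label <- character()
  run_label <- NA_character_; run_len <- 0L
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "Invalid") {
      out_frame <- c(out_frame, i); out_label <- c(out_label, "Invalid")
      run_label <- NA_character_; run_len <- 0L
      next
    }
    if (identical(lab, run_label)) run_len <- run_len + 1L
    else { run_label <- lab; run_len <- 1L }
    if (run_len == k) {
      out_frame <- c(out_frame, i); out_label <- c(out_label, lab)
    }
  }
  data.frame(frame = out_frame, label = out_label,
             stringsAsFactors = FALSE)
}

#' Trailing moving-average smoothing
#'
#' Element `i` is the mean of the trailing `min(i, window)` values, so the
#' output has the same length as the input (the window expands at the start).
#' Used to smooth face-contour metrics driving camera framing.
#'
#' @param values Numeric vector.
#' @param window Window length, `>= 1`.
#' @return Numeric vector, same length as `values`.
#' @examples
#' moving_average_smooth(c(0, 3, 6), window = 3)  # 0, 1.5, 3
#' @export
moving_average_smooth <- function(values, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop_domain("`window` must be >= 1")
  n <- length(values)
  if (n == 0L) return(numeric())
  cs <- cumsum(values)
  i <- seq_len(n)
  lo <- pmax(i - window, 0L)
  (cs - c(0, cs)[lo + 1L]) / (i - lo)
}

# Golden pose table: id, validity, name, detected marker ids, expected final
# pose.  Mirrors the occluder-validation protocol (four valid poses, five
# faults).
pose_table <- function() {
  data.frame(
    pose_id = 1:9,
    validity = c("Valid", "Valid", "Valid", "Valid",
                 "Invalid", "Invalid", "Invalid", "Invalid", "Invalid"),
    pose = c("Left", "Right", "Left Pinhole", "Right Pinhole",
             "Partial Eye Cover (L)", "Partial Eye Cover (R)",
             "Pinhole Partially Lowered (L)", "Pinhole Partially Lowered (R)",
             "No Occluder"),
    ids = I(list(1L, 2L, c(1L, 3L), c(2L, 4L), 1L, 2L, 1L, 4L, integer())),
    expected = c("Left", "Right", "Left_ph", "Right_ph",
                 "Invalid", "Invalid", "Left", "Right", "Invalid"),
    stringsAsFactors = FALSE)
}

square_box <- function(cx, cy, half) {
  cbind(c(cx - half, cx + half, cx + half, cx - half),
        c(cy - half, cy - half, cy + half, cy + half))
}

#' Synthesise a pose observation realising one golden-table row
#'
#' Builds marker boxes and iris landmarks on a 640x480 frame matching the
#' described occluder state, with seed-controlled pixel jitter small enough
#' to preserve the inside/outside relations.  Image convention: the frame
#' shows the subject, so the subject's RIGHT eye appears on the image left.
#'
#' @param pose_id Integer 1..9 (golden-table row).
#' @param geometry Optional list overriding `eye_left`, `eye_right` (image
#'   coordinates of the subject's left/right eye), `marker_half` (half box
#'   size) and `jitter` (max abs pixel jitter).
#' @param seed Integer seed for the jitter.
#' @return A [pose_observation()].
#' @export
synth_pose_fixture <- function(pose_id, geometry = list(), seed = 1L) {
  pose_id <- as.integer(pose_id)
  if (is.na(pose_id) || pose_id < 1L || pose_id > 9L)
    stop_domain("`pose_id` must be in 1..9")
  g <- utils::modifyList(
    list(eye_left = c(400, 220), eye_right = c(240, 220),
         marker_half = 28, jitter = 4), geometry)
  with_seed(seed, {
    j <- function() stats::runif(2, -g$jitter, g$jitter)
    eyeL <- g$eye_left + j(); eyeR <- g$eye_right + j()
    face <- square_box(mean(c(eyeL[1], eyeR[1])), 260, 140)
    boxes <- list(); irisL <- NULL; irisR <- NULL
    add_box <- function(id, center)
      boxes[[as.character(id)]] <<- square_box(center[1] + j()[1],
                                               center[2] + j()[2], g$marker_half)
    # Base-plate marker sits over the covered eye; pinhole flap markers sit
    # over the tested eye (fully lowered) or above it (partially lowered).
    if (pose_id %in% c(1L, 3L, 5L, 7L)) {          # left-eye test family
      covered <- eyeR; tested <- eyeL
      add_box(1L, covered)
      if (pose_id == 3L) add_box(3L, tested)
      irisL <- tested + j()                        # tested iris visible
      irisR <- if (pose_id == 5L)
        covered + c(3.2 * g$marker_half, 0) + j()  # partial cover: iris peeks out
      else NULL                                    # fully hidden
    } else if (pose_id %in% c(2L, 4L, 6L)) {       # right-eye test family
      covered <- eyeL; tested <- eyeR
      add_box(2L, covered)
      if (pose_id == 4L) add_box(4L, tested)
      irisR <- tested + j()
      irisL <- if (pose_id == 6L)
        covered + c(-3.2 * g$marker_half, 0) + j()
      else NULL
    } else if (pose_id == 8L) {                    # pinhole flap half-lowered (R)
      # Only id 4 detected, hovering above the right eye; left eye occluded
      # by the (undetected) base plate, so its iris is hidden.
      add_box(4L, eyeR - c(0, 3.5 * g$marker_half))
      irisR <- eyeR + j()
      irisL <- NULL
    }                                              # pose 9: nothing detected
    ids <- as.integer(names(boxes))
    pose_observation(marker_ids = ids, marker_boxes = boxes,
                     iris_left = irisL, iris_right = irisR,
                     face_box = face, frame_index = 0L)
  })
}
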