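#' The complex-figure element registry
#'
#' The Birmingham Cognitive Screen (BCoS) complex-figure copy task is scored
#' on 16 units: 15 standard elements (5 left, 5 right, 5 middle) each worth
#' up to 3 points (presence, correct shape, correct placement) and the middle
#' square worth up to 2 (presence, shape), for a 47-point maximum. The
#' global/local decomposition grades a different carving of the figure by
#' presence alone: 6 global features (the larger layout parts) and 14 local
#' features (the smaller details), i.e. 20 features in all.
#'
#' The two carvings overlap but do not coincide, so the registry holds one
#' row per *feature* (20 rows). Sixteen rows are themselves scoreable units
#' (`scoring` is `"presence_shape_placement"` or `"presence_shape"`); the
#' remaining four local features are sub-parts of a scoreable unit
#' (`scoring = "presence_only"`, `unit_id` names the parent unit) and
#' contribute to the local count but never to the 47-point total. Rows where
#' the global/local naming and the unit naming plausibly describe the same
#' ink (the global "left double bar" vs the left double-oblique-bars unit;
#' the global "right triangle" vs the right double-oblique/triangle unit)
#' are flagged in `ambiguous_name` rather than silently merged.
#'
#' @return A data.frame with columns `element_id`, `region` (left/right/
#'   middle), `level` (global/local), `scoring`, `unit_id`, `ambiguous_name`.
#' @examples
#' reg <- figure_elements()
#' table(reg$level)    # 6 global, 14 local
#' table(reg$scoring)  # 15 presence_shape_placement, 1 presence_shape, 4 presence_only
#' @export
figure_elements <- function() {
  reg <- rbind(
    # -- global features (6) -------------------------------------------------
    fe("middle_square",            "middle", "global", "presence_shape"),
    fe("left_rectangle",           "left",   "global", "presence_shape_placement"),
    fe("right_rectangle",          "right",  "global", "presence_shape_placement"),
    fe("left_double_bar",          "left",   "global", "presence_shape_placement", amb = TRUE),
    fe("right_triangle",           "right",  "global", "presence_shape_placement", amb = TRUE),
    fe("long_main_diagonal",       "middle", "global", "presence_shape_placement"),
    # -- local features that are themselves scoreable units (10) -------------
    fe("left_diagonal_end_three_bars", "left", "local", "presence_shape_placement"),
    fe("left_horizontal_bar",      "left",   "local", "presence_shape_placement"),
    fe("left_circle",              "left",   "local", "presence_shape_placement"),
    fe("right_diagonal_end_s",     "right",  "local", "presence_shape_placement"),
    fe("right_horizontal_bar",     "right",  "local", "presence_shape_placement"),
    fe("right_double_dot",         "right",  "local", "presence_shape_placement"),
    fe("arrow",                    "middle", "local", "presence_shape_placement"),
    fe("left_curve",               "middle", "local", "presence_shape_placement"),
    fe("right_curve",              "middle", "local", "presence_shape_placement"),
    fe("cross",                    "middle", "local", "presence_shape_placement"),
    # -- local sub-features of a scoreable unit (4) --------------------------
    fe("top_left_diagonal_bar",    "left",  "local", "presence_only", unit = "left_double_bar", amb = TRUE),
    fe("parallel_bar_below",       "left",  "local", "presence_only", unit = "left_double_bar", amb = TRUE),
    fe("triangle_right_side",      "right", "local", "presence_only", unit = "right_triangle", amb = TRUE),
    fe("triangle_left_side",       "right", "local", "presence_only", unit = "right_triangle", amb = TRUE)
  )
  validate_registry(reg)
  reg
}

#' @noRd
fe <- function(id, region, level, scoring, unit = id, amb = FALSE) {
  data.frame(element_id = id, region = region, level = level, scoring = scoring,
             unit_id = unit, ambiguous_name = amb, stringsAsFactors = FALSE)
}

#' @noRd
validate_registry <- function(reg) {
  if (anyDuplicated(reg$element_id)) stop("duplicate element ids in registry")
  units <- reg[reg$scoring != "presence_only", ]
  if (sum(units$scoring == "presence_shape_placement") != 15L)
    stop("registry must contain exactly 15 presence/shape/placement units")
  if (sum(units$scoring == "presence_shape") != 1L)
    stop("registry must contain exactly one presence/shape unit (the middle square)")
  if (sum(reg$level == "global") != 6L || sum(reg$level == "local") != 14L)
    stop("registry must carry 6 global and 14 local features")
  invisible(reg)
}

#' Build a drawing record
#'
#' A drawing record states, for every feature in [figure_elements()], whether
#' it was drawn, drawn with the correct shape, and drawn in the correct
#' place. Credit implies presence: `shape_correct` or `placement_correct`
#' without `present` is rejected.
#'
#' @param df A data.frame with columns `element_id`, `present`,
#'   `shape_correct`, `placement_correct` (logical or 0/1), one row per
#'   registry feature, each feature exactly once.
#' @return A `drawing_record` object.
#' @seealso [perfect_record()], [blank_record()], [read_drawing_record()]
#' @export
drawing_record <- function(df) {
  reg <- figure_elements()
  need <- c("element_id", "present", "shape_correct", "placement_correct")
  if (!all(need %in% names(df)))
    stop("record needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  for (col in need[-1]) df[[col]] <- as.logical(df[[col]])
  if (any(is.na(df$present) | is.na(df$shape_correct) | is.na(df$placement_correct)))
    stop("record contains missing values")
  unknown <- setdiff(df$element_id, reg$element_id)
  if (length(unknown)) stop("unknown element id(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(reg$element_id, df$element_id)
  if (length(missing)) stop("missing element id(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$element_id))
    stop("duplicated element id(s) in record")
  bad <- (df$shape_correct | df$placement_correct) & !df$present
  if (any(bad))
    stop("credit without presence for: ", paste(df$element_id[bad], collapse = ", "))
  df <- df[match(reg$element_id, df$element_id), ]
  rownames(df) <- NULL
  structure(df, class = c("drawing_record", "data.frame"))
}

#' @rdname drawing_record
#' @export
perfect_record <- function() {
  reg <- figure_elements()
  drawing_record(data.frame(element_id = reg$element_id, present = TRUE,
                            shape_correct = TRUE, placement_correct = TRUE))
}

#' @rdname drawing_record
#' @export
blank_record <- function() {
  reg <- figure_elements()
  drawing_record(data.frame(element_id = reg$element_id, present = FALSE,
                            shape_correct = FALSE, placement_correct = FALSE))
}

#' Read a drawing record from delimited text
#'
#' Expects a header row and the four record columns; `present` etc. may be
#' logical (`TRUE`/`FALSE`) or 0/1.
#'
#' @param path File path.
#' @param sep Field separator, default tab.
#' @return A [drawing_record].
#' @export
read_drawing_record <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  drawing_record(utils::read.table(path, header = TRUE, sep = sep,
                                   stringsAsFactors = FALSE))
}

#' Complex-figure scores
#'
#' `total_score()` applies the full 47-point scheme: presence + shape +
#' placement over the 15 standard units plus presence + shape for the middle
#' square. `global_score()` (max 6) and `local_score()` (max 14) count
#' feature presence only — shape and placement are deliberately ignored in
#' the global/local decomposition. `percent_scores()` rescales both to
#' percentages of their maxima so they are comparable despite the unequal
#' feature counts.
#'
#' @param rec A [drawing_record].
#' @return An integer score, or for `percent_scores()` a named numeric vector
#'   `c(global_pct =, local_pct =)`.
#' @examples
#' total_score(perfect_record())   # 47
#' global_score(perfect_record())  # 6
#' local_score(perfect_record())   # 14
#' @export
total_score <- function(rec) {
  stopifnot(inherits(rec, "drawing_record"))
  reg <- figure_elements()
  psp <- reg$scoring == "presence_shape_placement"
  ps  <- reg$scoring == "presence_shape"
  sum(rec$present[psp] + rec$shape_correct[psp] + rec$placement_correct[psp]) +
    sum(rec$present[ps] + rec$shape_correct[ps])
}

#' @rdname total_score
#' @export
global_score <- function(rec) {
  stopifnot(inherits(rec, "drawing_record"))
  sum(rec$present[figure_elements()$level == "global"])
}

#' @rdname total_score
#' @export
local_score <- function(rec) {
  stopifnot(inherits(rec, "drawing_record"))
  sum(rec$present[figure_elements()$level == "local"])
}

#' @rdname total_score
#' @export
percent_scores <- function(rec) {
  c(global_pct = 100 * global_score(rec) / 6,
    local_pct  = 100 * local_score(rec) / 14)
}
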