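# Worked-example fixtures: the published VOX response matrix, the
# four-axis profile of the worked shape-descriptor example, and the
# longitudinal / cross-speaker descriptor tables, regenerated in code.

#' Built-in worked-example data
#'
#' Returns the small published datasets the package's worked examples are
#' based on, regenerated programmatically:
#'
#' * `"table2"` — the trial-level VOX assessment of a 3-year-old boy with
#'   ASD: six response forms ("iPad", "Guitar", "Spider", "Lion",
#'   "Phone", "Step on it") each probed under the four operant
#'   conditions; operant totals tact 5, mand 2, echoic 5, sequelic 1.
#' * `"fig4"` — the axis values of the worked shape-descriptor example
#'   (tact 12, mand 10, echoic 12, sequelic 8; area 220, centroid
#'   (1.33, -0.67)).
#' * `"table3"` — the biannual longitudinal descriptor table (ages 3:4 to
#'   5:5) with printed `R` and `Q` rows. The published area row is
#'   typeset as a run-on; the values here (4, 84, 80, 220, 288) are the
#'   unique reading consistent with `Q = A(C - R)` at `C = 12`.
#' * `"table4"` — the cross-speaker descriptor comparison of four
#'   children (charts A-D), including the two centroids reported in the
#'   figure notes that accompany it.
#'
#' @param name One of `"table2"`, `"fig4"`, `"table3"`, `"table4"`.
#' @return A `vox_dataset`, [axis_values()], or tibble as described.
#' @examples
#' operant_totals(vox_fixture("table2"))
#' @export
vox_fixture <- function(name = c("table2", "fig4", "table3", "table4")) {
  name <- match.arg(name)
  switch(name,
    table2 = fixture_table2(),
    fig4 = axis_values(tact = 12, mand = 10, echoic = 12, sequelic = 8),
    table3 = tibble::tibble(
      time = 1:5,
      age = c("3:4", "4:0", "4:5", "4:11", "5:5"),
      A = c(4, 84, 80, 220, 288),
      R = c(1.49, 3.33, 2.40, 1.49, 0.00),
      Q = c(42.04, 728.00, 767.70, 2312.04, 3456.00)),
    table4 = tibble::tibble(
      child = c("A", "B", "C", "D"),
      sex = c("Male", "Female", "Female", "Male"),
      race_ethnicity = c("African American/Non-Hispanic", "White/Hispanic",
                         "African American/Hispanic", "White/Hispanic"),
      home_languages = c("English", "English/Spanish", "English", "Spanish"),
      age = c("4:5", "6:0", "3:9", "3:10"),
      diagnosis = c("ASD", "ASD", "ASD", "neurotypical"),
      A = c(146.67, 154.00, 1.00, 272),
      R = c(3.14, 3.40, 0.75, 0.44),
      Q = c(1299.07, 1324.50, 11.25, 3143.11),
      centroid_x = c(3.0, 3.33, -1 / 3, 0.5),
      centroid_y = c(-0.5, 0.67, -2 / 3, 0.0))
  )
}

fixture_table2 <- function() {
  forms <- c("iPad", "Guitar", "Spider", "Lion", "Phone", "Step on it")
  m <- matrix(c(0, 0, 1, 0,   # iPad
                1, 0, 1, 0,   # Guitar
                1, 0, 1, 1,   # Spider
                1, 1, 1, 0,   # Lion
                1, 0, 0, 0,   # Phone
                1, 1, 1, 0),  # Step on it
              nrow = 6, byrow = TRUE,
              dimnames = list(forms, vox_operants))
  vox_dataset(
    tibble::tibble(
      speaker_id = "child_t2",
      session = 1L,
      response_form = rep(forms, each = 4),
      condition = rep(vox_operants, times = 6),
      emitted = as.integer(t(m))),
    speaker = speaker_record("child_t2", age = "3:4", sex = "Male",
                             diagnosis = "ASD"))
}
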