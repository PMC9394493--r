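# Design construction shared by the generator, the landmarking stack and the
# linear-predictor methods. All columns are centred at the reference subject
# so the reference linear predictor is exactly zero at every landmark.

# Raw -> centred baseline design matrix (n x 9), canonical column order.
baseline_design <- function(baseline) {
  ref <- reference_subject()
  edu <- as.character(baseline$education)
  m <- cbind(
    height     = baseline$height - ref$height,
    body_mass  = baseline$body_mass - ref$body_mass,
    age        = baseline$age - ref$age,
    education1 = as.numeric(edu == "level1"),
    education2 = as.numeric(edu == "level2"),
    body_fat   = baseline$body_fat - ref$body_fat,
    cooper     = baseline$cooper - ref$cooper,
    pushups10  = baseline$pushups / 10 - ref$pushups / 10,
    situps10   = baseline$situps / 10 - ref$situps / 10
  )
  if (anyNA(m)) {
    bad <- colnames(m)[colSums(is.na(m)) > 0]
    stop("missing baseline covariate(s): ", paste(bad, collapse = ", "),
         " (impute first)")
  }
  m
}

# Landmark interaction code: the integer entering Z(s) * code(s).
landmark_code <- function(s, coding = c("s_minus_1", "s")) {
  coding <- match.arg(coding)
  if (coding == "s_minus_1") s - 1 else s
}

# Centred time-varying design (n x length(items)): Likert items minus the
# neutral reference response; pain indicator left as 0/1 (reference 0).
tv_design <- function(z, items) {
  ref <- reference_subject()
  m <- sapply(items, function(it) {
    v <- z[[it]]
    if (it == "pain") v else v - ref[[it]]
  })
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, items))
  m
}
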