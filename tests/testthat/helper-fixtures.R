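# Small in-code fixtures shared across test files.

make_cohort <- function(site, values, features = paste0("f", seq_len(ncol(values)))) {
  values <- as.matrix(values)
  colnames(values) <- features
  as_cohort(dplyr::bind_cols(
    tibble::tibble(patient_id = sprintf("%s-%03d", site, seq_len(nrow(values)))),
    tibble::as_tibble(values)
  ), site = site)
}

# uniform unit-square cohort and its copy shrunk about the center
square_cohorts <- function(n = 1000, shrink = 0.5, seed = 1) {
  set.seed(seed)
  a <- cbind(runif(n), runif(n))
  b <- 0.5 + (a - 0.5) * shrink
  list(A = make_cohort("A", a, c("x", "y")),
       B = make_cohort("B", b, c("x", "y")))
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
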