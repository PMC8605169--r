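# In-code CSV fixtures for the reader tests.

write_iqc_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("lab,analyte,level,run,value", lines), path)
  path
}

write_eqa_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("lab,analyte,level,replicate,value,target", lines), path)
  path
}

# 2 labs x 1 analyte x 2 levels x 3 runs, runs deliberately unordered for
# one key so sorting is exercised.
iqc_fixture_small <- function() {
  write_iqc_fixture(c(
    "Lab A,K,level1,2,25.2",
    "Lab A,K,level1,1,25.0",
    "Lab A,K,level1,3,24.8",
    "Lab A,K,level2,1,55.0",
    "Lab A,K,level2,2,55.5",
    "Lab A,K,level2,3,54.5",
    "Lab B,K,level1,1,25.1",
    "Lab B,K,level1,2,24.9",
    "Lab B,K,level1,3,25.0",
    "Lab B,K,level2,1,56.0",
    "Lab B,K,level2,2,55.0",
    "Lab B,K,level2,3,54.0"
  ))
}

eqa_fixture_one_key <- function(values = c(10.2, 10.1, 10.3, 10.2, 10.2),
                                target = 10) {
  write_eqa_fixture(sprintf("Lab A,K,level1,%d,%s,%s",
                            seq_along(values), values, target))
}

# A tiny scenario row for generator tests.
scenario_row <- function(true_cv = 4, true_bias = 2, n_iqc = 360,
                         n_eqa = 5, true_mean = 25, lab = "Lab A",
                         analyte = "K", level = "level1") {
  tibble::tibble(
    lab = lab, analyte = analyte, level = level,
    true_mean = true_mean, eqa_target = true_mean,
    true_cv = true_cv, true_bias = true_bias, tea = 29,
    n_iqc_values = n_iqc, n_eqa_replicates = n_eqa
  )
}
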