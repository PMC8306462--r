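# Shared fixtures, all built in code at test time.

# published 2x2 counts: mutation arm (13 pCR / 11 non-pCR),
# reference arm (48 / 71)
paper_counts <- list(arm1 = c(13L, 11L), arm2 = c(48L, 71L))
paper_table <- function() two_by_two(13, 11, 48, 71)
paper_posteriors <- function() list(arm1 = beta_params(17, 17),
                                    arm2 = beta_params(51, 78))

# write a cohort CSV to a temp file; returns the path
write_temp_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# a small synthetic cohort data.frame in the raw-CSV schema
make_csv_cohort <- function(n = 143, seed = 42) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    brca1 <- sample(c("neg", "pos"), n, replace = TRUE, prob = c(0.83, 0.17))
    data.frame(id = sprintf("P%03d", seq_len(n)),
               brca1 = brca1,
               pcr = rbinom(n, 1, ifelse(brca1 == "pos", 0.54, 0.40)),
               age = round(rnorm(n, ifelse(brca1 == "pos", 47, 57), 12.7), 1))
  })
}

paper_analysis_config <- function(...) {
  utils::modifyList(
    list(counts = paper_counts,
         arm_names = c("BRCA1_pos", "BRCA1_neg")),
    list(...))
}
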