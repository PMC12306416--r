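# Small in-code fixtures shared across tests.

# Three complete, mutually consistent specimens with hand-picked round values.
toy_dataset <- function() {
  mfs_data(data.frame(
    specimen_id = c("a", "b", "c"),
    taxon = c("ta", "tb", "tc"),
    group = c("digger", "terrestrial", "climber"),
    source = "direct", focal = FALSE,
    HL = c(10, 20, 15), HMLD = c(1, 1.6, 1.2), HEB = c(3, 4.4, 3.9),
    UL = c(11, 21, 16), FUL = c(8.8, 17, 13), UMLD = c(1.1, 1.4, 1.3),
    OL = c(2.2, 4, 3), RL = c(9, 18, 14), RMLD = c(0.9, 1.5, 1.1),
    MTCIII_L = c(5, 8, 7), WFA = c(1.2, 1.5, 1.6),
    estimated = "", stringsAsFactors = FALSE))
}

# A complete generated dataset reused by several tests (fixed seed).
study_data <- function(seed = 42) make_study_like_dataset(seed = seed)

expect_close <- function(x, y, tol) expect_true(all(abs(x - y) <= tol))
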