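# Published cohort values, transcribed independently of the packaged fixture
# so the fixture content itself is under test.
published <- list(
  qrs = c(82, 160, 120, 108, 85, 98, 124, 117, 92, 74, 83, 145, 83, 92.5, 146, 122),
  qt  = c(428, 400, 352, 446, 411, 392, 344, 479, 360, 357, 620, 727, 600, 572, 544, 650),
  qtc = c(494, 487, 470, 446, 515, 496, 506, 491, 502, 535, 670, 650, 670, 695, 534, 657),
  hr  = c(80, 85, 107, 60, 93, 96, 130, 63, 117, 90, 75, 48, 75, 83, 58, 59),
  ratio = c(0.17, 0.33, 0.26, 0.24, 0.17, 0.20, 0.25, 0.24, 0.18, 0.14,
            0.12, 0.22, 0.12, 0.13, 0.27, 0.19),
  vt_vf = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE,
            TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
  age = c(20, 21, 23, 23, 24, 25, 31, 33, 35, 40, 48, 52, 54, 81, 82, 89),
  dose = c(1.8, 11.6, 0.22, 0.92, 1.8, NA, 0.4, 0.4, NA, 0.08, 0.04, 0.14,
           NA, NA, 1.6, 0.04)
)

# population (divide-by-n) standard deviation, written out as the oracle
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(sum((x - mean(x))^2) / length(x))
}

# Exact two-sided permutation p-value for the pooled-variance t statistic:
# enumerates every assignment of n_a labels, computing t from group sums.
# Independent of the package's pooled_t_test implementation path.
perm_t_pvalue <- function(a, b) {
  x <- c(a, b)
  n <- length(x)
  na <- length(a)
  nb <- length(b)
  idx <- utils::combn(n, na)
  sum_x <- sum(x)
  sum_x2 <- sum(x^2)
  t_from_selection <- function(s_a) {
    m_a <- s_a / na
    m_b <- (sum_x - s_a) / nb
    ss_within <- sum_x2 - na * m_a^2 - nb * m_b^2
    sp2 <- ss_within / (na + nb - 2)
    (m_a - m_b) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  s_all <- colSums(matrix(x[idx], nrow = na))
  t_all <- t_from_selection(s_all)
  t_obs <- t_from_selection(sum(a))
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}
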