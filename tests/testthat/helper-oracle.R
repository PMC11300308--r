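# Independent brute-force stage oracle: literally evaluates the printed
# combination list of each stage block in severity order, plus the
# modification that significant weight loss reaching no refractory
# combination is cachectic. Written first, kept independent of the
# package's rule-table implementation.
oracle_stage <- function(A, B, C, D, E, F, S) {
  if ((A && D && F) || (B && D && F) || (A && B && D && F) ||
      (S && D) || (S && E) || (S && D && F)) {
    return("RCa")
  }
  if ((A && D && E) || (B && D && E) || (A && B && D && E) || D) {
    return("Ca")
  }
  if ((A && B) || (A && C) || (B && C) || (A && B && C)) {
    return("PCa")
  }
  "NCa"
}

# all 2^7 flag patterns
all_flag_patterns <- function() {
  g <- expand.grid(A = c(FALSE, TRUE), B = c(FALSE, TRUE),
                   C = c(FALSE, TRUE), D = c(FALSE, TRUE),
                   E = c(FALSE, TRUE), F = c(FALSE, TRUE),
                   alb_severe = c(FALSE, TRUE))
  g
}
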