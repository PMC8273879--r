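# Congruent-production priming effects (first-member scale) from a
# condition summary: proportion of first-member productions after
# first-member primes minus after second-member primes, per
# grammaticality level.
summary_priming <- function(s, alternation = c("A", "P")) {
  cell <- function(st, gr) s$mean[s$structure == st & s$grammatical == gr]
  c(C = cell(alternation[[1]], "C") - (1 - cell(alternation[[2]], "C")),
    I = cell(alternation[[1]], "I") - (1 - cell(alternation[[2]], "I")))
}

# Small hand-built response table.
toy_responses <- function(responses, structures, grammatical = NULL,
                          participant = NULL) {
  n <- length(responses)
  data.frame(
    participant = if (is.null(participant)) rep("p1", n) else participant,
    trial = seq_len(n),
    prime_structure = structures,
    grammatical = if (is.null(grammatical)) rep("C", n) else grammatical,
    semantic_correct = rep(NA_character_, n),
    response = responses,
    stringsAsFactors = FALSE
  )
}

# One-trial stimulus.
stim <- function(structure, grammatical = "C",
                 error_position = if (grammatical == "C") "none"
                 else "pre_structure") {
  list(structure = structure, grammatical = grammatical,
       error_position = error_position, semantic_correct = "C")
}
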