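# Random rule-set generator for property tests (uses the current RNG state).

random_expr <- function(depth = 3) {
  v <- uv_vocabulary()
  leaf <- function() {
    pick <- sample.int(5L, 1L)
    if (pick == 1L) finding_is(sample(v$code[v$kind == "finding"], 1),
                               sample(c("present", "absent"), 1))
    else if (pick == 2L) test_is(sample(v$code[v$kind == "test"], 1),
                                 sample(c("positive", "negative"), 1))
    else if (pick == 3L) course_in(sample(c("acute", "recurrent_acute", "chronic",
                                            "chronic_after_recurrent_acute"),
                                          sample.int(3L, 1L)))
    else if (pick == 4L) laterality_in(sample(c("unilateral", "bilateral",
                                                "alternating_unilateral"),
                                              sample.int(2L, 1L)))
    else grade_lt("vitreous_cells_anterior", "anterior_chamber_cells")
  }
  build <- function(d) {
    if (d == 0L || stats::runif(1) < 0.4) return(leaf())
    op <- sample(c("and", "or", "not"), 1)
    if (op == "not") rx_not(build(d - 1L))
    else do.call(if (op == "and") rx_and else rx_or,
                 lapply(seq_len(sample(2:3, 1)), function(i) build(d - 1L)))
  }
  build(depth)
}

random_ruleset <- function(id) {
  rule_set(id, paste("random disease", id),
           sample(uv_anatomic_classes(), 1), random_expr(),
           exclusions = lapply(seq_len(sample(0:2, 1)), function(i) random_expr(2)),
           provenance = "property test")
}
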