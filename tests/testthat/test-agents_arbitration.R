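kg <- default_kg()
vg <- validation_vignette()
feats <- extract_features(vg)

test_that("confidence-weighted voting sums confidences per option", {
  r <- function(opt, conf, id = paste0("a", opt, conf)) {
    agent_response(id, opt, conf)
  }
  expect_equal(confidence_weighted_vote(list(r("C", 0.96), r("C", 0.95))),
               c(C = 1.91))
  expect_equal(confidence_weighted_vote(list(r("A", 0.5))), c(A = 0.5))
  expect_equal(confidence_weighted_vote(list(r("A", 0.9), r("B", 0.4))),
               c(A = 0.9, B = 0.4))
  expect_error(confidence_weighted_vote(list()),
               class = "tg18_validation_error")
})

test_that("the symbolic agent answers the validation case and abstains on ties", {
  r <- symbolic_agent_answer(vg, kg)
  expect_identical(r$selected_option, "C")
  expect_equal(r$confidence, 1.0)
  expect_false(r$abstained)
  # duplicate best option -> tie -> abstention with zero confidence
  opts <- vg$options
  opts[["E"]] <- opts[["C"]]
  tied <- clinical_vignette("tied", text = vg$text, question = vg$question,
                            options = opts)
  rt <- symbolic_agent_answer(tied, kg)
  expect_true(rt$abstained)
  expect_equal(rt$confidence, 0)
  expect_error(symbolic_agent_answer(
    clinical_vignette("one", text = vg$text,
                      options = c(A = "Only option")), kg),
    class = "tg18_validation_error")
})

test_that("simulated agents hit their planted error rates", {
  pool <- LETTERS[1:5]
  g0 <- vapply(1:25, function(s) {
    simulated_agent_answer(pool, "C", error_rate = 0, seed = s)$selected_option
  }, character(1))
  expect_true(all(g0 == "C"))
  g1 <- vapply(1:25, function(s) {
    simulated_agent_answer(pool, "C", error_rate = 1, seed = s)$selected_option
  }, character(1))
  expect_true(all(g1 != "C"))
  n <- 10000
  hits <- vapply(seq_len(n), function(s) {
    simulated_agent_answer(pool, "B", error_rate = 0.2,
                           seed = s)$selected_option == "B"
  }, logical(1))
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(mean(hits) - 0.8), 3 * se)
  # confidences always in [0, 1] and reproducible under the same seed
  r1 <- simulated_agent_answer(pool, "C", 0.2, seed = 99)
  r2 <- simulated_agent_answer(pool, "C", 0.2, seed = 99)
  expect_identical(r1$confidence, r2$confidence)
  expect_true(r1$confidence >= 0 && r1$confidence <= 1)
})

test_that("constraint checking rejects undergrading and contraindicated surgery", {
  # Grade II criteria satisfied, response claims mild disease
  f_g2 <- features_with(murphy_sign = TRUE, temperature = 38.6, wbc = 22400,
                        wall_thickness = 5)
  under <- agent_response("a1", "A", 0.9,
                          option_text = "Grade I (mild) acute cholecystitis managed conservatively")
  v <- check_constraints(under, f_g2, kg)
  expect_gte(length(v), 1L)
  expect_true(any(vapply(v, `[[`, character(1), "type") ==
                    "severity_undergrade"))
  # Grade III with vasopressor-dependent hypotension, immediate surgery claimed
  f_g3 <- features_with(murphy_sign = TRUE, temperature = 38.6, wbc = 15000,
                        norepinephrine_any = TRUE, wall_thickness = 6)
  surg <- agent_response("a2", "A", 0.8,
                         option_text = "Emergency laparoscopic cholecystectomy")
  v2 <- check_constraints(surg, f_g3, kg)
  expect_true(any(vapply(v2, `[[`, character(1), "type") ==
                    "surgery_contraindicated"))
  # a fully concordant response passes
  conc <- agent_response("a3", "C", 0.95,
                         option_text = vg$options[["C"]])
  expect_length(check_constraints(conc, feats, kg), 0L)
  # undecodable claims are logged indeterminate and treated admissible
  bare <- agent_response("a4", "B", 0.5)
  v3 <- check_constraints(bare, feats, kg)
  expect_length(v3, 0L)
  expect_true(attr(v3, "indeterminate"))
})

test_that("uncertainty scoring behaves at its boundary cases", {
  agree <- list(agent_response("a1", "C", 0.96),
                agent_response("a2", "C", 0.95))
  expect_equal(quantify_uncertainty(agree, n_samples = 500, seed = 3), 0)
  close <- list(agent_response("a1", "A", 0.51),
                agent_response("a2", "B", 0.49))
  u1 <- quantify_uncertainty(close, n_samples = 1000, seed = 5,
                             perturb_sd = 0.1)
  u2 <- quantify_uncertainty(close, n_samples = 1000, seed = 5,
                             perturb_sd = 0.1)
  expect_identical(u1, u2)
  expect_gt(u1, 0); expect_lt(u1, 1)
  u3 <- quantify_uncertainty(close, n_samples = 1, seed = 7)
  expect_true(u3 %in% c(0, 1))
})

test_that("arbitration: agreement averages confidences; constraints dominate", {
  r1 <- agent_response("agent1", "C", 0.96, option_text = vg$options[["C"]])
  r2 <- agent_response("agent2", "C", 0.95, option_text = vg$options[["C"]])
  cons <- arbitrate(list(r1, r2), feats, kg, vignette = vg)
  expect_identical(cons$final_option, "C")
  expect_equal(cons$final_confidence, 0.955)
  expect_equal(cons$vote_tally, c(C = 1.91))
  # a violating response can never win while an admissible one exists
  bad <- agent_response("agent1", "A", 0.9,
                        option_text = "Emergency laparoscopic cholecystectomy")
  ok <- agent_response("agent2", "E", 0.6,
                       option_text = vg$options[["E"]])
  c2 <- arbitrate(list(bad, ok), feats, kg, vignette = vg)
  expect_identical(c2$final_option, "E")
  expect_gte(length(c2$violations[["agent1"]]), 1L)
  # when every response violates, the symbolic engine answers
  bad2 <- agent_response("agent2", "B", 0.8,
                         option_text = vg$options[["B"]])
  c3 <- arbitrate(list(bad, bad2), feats, kg, vignette = vg)
  expect_identical(c3$final_option, "C")
  expect_match(c3$resolution_note, "symbolic")
  expect_error(arbitrate(list()), class = "tg18_validation_error")
})

test_that("arbitration ties break by option label and flag low confidence", {
  rA <- agent_response("agent1", "A", 0.8)
  rB <- agent_response("agent2", "B", 0.8)
  cons <- arbitrate(list(rA, rB))
  expect_identical(cons$final_option, "A")
  expect_true(cons$low_confidence)
  # exhaustive two-agent enumeration: winner always has max admissible vote
  for (o1 in c("A", "B")) for (o2 in c("A", "B")) {
    for (c1 in c(0.4, 0.7)) for (c2 in c(0.4, 0.7)) {
      cc <- arbitrate(list(agent_response("x", o1, c1),
                           agent_response("y", o2, c2)))
      tal <- cc$vote_tally
      expect_true(tal[[cc$final_option]] == max(tal))
    }
  }
})

test_that("arbitration is permutation invariant and reproducible", {
  rs <- list(agent_response("agent1", "B", 0.7,
                            option_text = vg$options[["B"]]),
             agent_response("agent2", "C", 0.9,
                            option_text = vg$options[["C"]]),
             agent_response("agent3", "C", 0.6,
                            option_text = vg$options[["C"]]))
  c1 <- arbitrate(rs, feats, kg, vignette = vg)
  c2 <- arbitrate(rev(rs), feats, kg, vignette = vg)
  expect_identical(c1$final_option, c2$final_option)
  expect_identical(c1$final_confidence, c2$final_confidence)
  expect_identical(c1$uncertainty, c2$uncertainty)
  c3 <- arbitrate(rs, feats, kg, vignette = vg)
  expect_identical(c1, c3)
})

test_that("the symbolic agent is run-to-run consistent (kappa 1)", {
  bank <- generate_question_bank(generation_spec(seed = 77))
  items <- bank$items[bank$truth$category %in%
                        c("calculous", "acalculous", "complicated")]
  runs <- lapply(1:3, function(run) {
    vapply(items, function(v) {
      r <- symbolic_agent_answer(v, kg)
      if (isTRUE(r$abstained)) "abstain" else r$selected_option
    }, character(1))
  })
  expect_identical(runs[[1]], runs[[2]])
  expect_identical(runs[[1]], runs[[3]])
  expect_gte(length(unique(runs[[1]])), 2L)
  expect_equal(cohen_kappa(runs[[1]], runs[[2]])$kappa, 1.0)
  # and it matches the planted gold on these acute items
  gold <- bank$truth$gold[bank$truth$category %in%
                            c("calculous", "acalculous", "complicated")]
  expect_identical(unname(runs[[1]]), unname(gold))
})
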