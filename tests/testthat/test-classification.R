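test_that("evidence precedence resolves single variants correctly", {
  # R1: premature truncation is decisive
  q266 <- evidence_record("796C>T", "nonsense", case_carriers = 1,
                          case_n = 448, control_carriers = 0,
                          control_n = 1588)
  call <- classify_variant(q266)
  expect_equal(call$verdict, "pathogenic")
  expect_equal(call$rule_fired, "R1_truncating")

  # R2: canonical splice with aberrant truncating transcript
  spl <- evidence_record("395-2A>G", "splice_canonical",
                         splice_transcript = "aberrant_truncating")
  expect_equal(classify_variant(spl)$verdict, "pathogenic")
  expect_equal(classify_variant(spl)$rule_fired, "R2_splice")

  # R2: normal transcript analysis clears any splice-adjacent variant
  benign <- evidence_record("868-12_868-11del", "intronic",
                            splice_transcript = "normal")
  expect_equal(classify_variant(benign)$verdict, "neutral")

  # canonical splice without transcript evidence cannot be resolved
  expect_warning(
    unresolved <- classify_variant(
      evidence_record("395-2A>G", "splice_canonical")),
    class = "famvar_no_evidence_warning")
  expect_equal(unresolved$verdict, "vus")

  # R3: partial activity loss is pathogenic even with normal-looking counts
  a195 <- evidence_record("583G>T", "missense",
                          helicase_class = "partial_loss",
                          case_carriers = 1, case_n = 448,
                          control_carriers = 0, control_n = 1588)
  expect_equal(classify_variant(a195)$verdict, "pathogenic")
  expect_equal(classify_variant(a195)$rule_fired, "R3_function")

  # R3: normal activity is neutral despite control presence
  h461 <- evidence_record("1382A>G", "missense", helicase_class = "normal",
                          case_carriers = 1, case_n = 448,
                          control_carriers = 1, control_n = 1588)
  expect_equal(classify_variant(h461)$verdict, "neutral")

  # control presence never overrides complete functional loss
  r455 <- evidence_record("1363C>T", "missense",
                          helicase_class = "complete_loss",
                          case_carriers = 1, case_n = 448,
                          control_carriers = 1, control_n = 1588)
  expect_equal(classify_variant(r455)$verdict, "pathogenic")

  # R4: start-loss with no functional data, similar frequencies, own
  # control denominator (748)
  m1t <- evidence_record("2T>C", "start_loss", case_carriers = 4,
                         case_n = 448, control_carriers = 9,
                         control_n = 748)
  call <- classify_variant(m1t, alpha_sim = 0.05)
  expect_equal(call$verdict, "neutral")
  expect_equal(call$rule_fired, "R4_frequency")
  expect_gte(call$p_similar, 0.05)

  # R4: dissimilar frequencies stay unresolved, not pathogenic
  rare <- evidence_record("9A>G", "missense", case_carriers = 12,
                          case_n = 100, control_carriers = 0,
                          control_n = 1000)
  expect_equal(classify_variant(rare)$verdict, "vus")

  # default: no functional data, no counts
  bare <- evidence_record("9A>G", "missense")
  expect_equal(classify_variant(bare)$verdict, "vus")
  expect_equal(classify_variant(bare)$rule_fired, "default")
})

test_that("the packaged screen table classifies to 9 pathogenic, 6 neutral", {
  res <- classify_table(screen_evidence())
  expect_equal(res$n_pathogenic, 9L)
  expect_equal(res$n_neutral, 6L)
  expect_equal(res$n_vus, 0L)
  expect_setequal(res$pathogenic_variants,
                  c("L128X", "W172X", "Q266X", "G132fs", "A195S", "R215Q",
                    "R455C", "M458K", "T562I"))
  # rule attribution: 3 truncating, 1 splice, 5 functional pathogenic
  path <- res$calls[res$calls$verdict == "pathogenic", ]
  expect_equal(sum(path$rule_fired == "R1_truncating"), 3)
  expect_equal(sum(path$rule_fired == "R2_splice"), 1)
  expect_equal(sum(path$rule_fired == "R3_function"), 5)
})

test_that("classification is order-invariant and rejects duplicate keys", {
  ev <- screen_evidence()
  base <- classify_table(ev)
  perm <- classify_table(ev[rev(seq_len(nrow(ev))), ])
  expect_equal(perm$n_pathogenic, base$n_pathogenic)
  expect_equal(perm$n_neutral, base$n_neutral)
  expect_setequal(perm$pathogenic_variants, base$pathogenic_variants)

  expect_error(classify_table(rbind(ev, ev[1, ])),
               class = "famvar_validation_error")

  empty <- classify_table(ev[0, ])
  expect_equal(empty$n_pathogenic + empty$n_neutral + empty$n_vus, 0L)
})

test_that("rules are total and monotone in functional evidence", {
  effects <- c("nonsense", "frameshift", "splice_canonical",
               "splice_region", "intronic", "missense", "start_loss",
               "synonymous")
  hel <- c("not_done", "normal", "partial_loss", "complete_loss")
  spl <- c("not_done", "normal", "aberrant_truncating")
  rank <- c(not_done = 0, normal = 1, partial_loss = 2, complete_loss = 3)
  for (e in effects) for (s in spl) {
    verdicts <- character(0)
    for (h in hel) {
      call <- suppressWarnings(classify_variant(
        evidence_record("1A>G", e, helicase_class = h,
                        splice_transcript = s, case_carriers = 2,
                        case_n = 100, control_carriers = 3,
                        control_n = 150)))
      expect_true(call$verdict %in% c("pathogenic", "neutral", "vus"))
      expect_length(call$rule_fired, 1)
      verdicts <- c(verdicts, call$verdict)
    }
    # upgrading evidence normal -> partial -> complete never demotes
    # pathogenic to neutral
    states <- verdicts[match(c("normal", "partial_loss", "complete_loss"),
                             hel)]
    for (i in seq_len(length(states) - 1))
      expect_false(states[i] == "pathogenic" && states[i + 1] == "neutral",
                   label = sprintf("effect %s, transcript %s", e, s))
  }
})

test_that("alpha_sim controls the frequency-similarity verdict", {
  ev <- screen_evidence()
  m1t <- ev[ev$protein_change == "M1T", ]
  expect_equal(classify_variant(m1t, alpha_sim = 0.05)$verdict, "neutral")
  expect_equal(classify_variant(m1t, alpha_sim = 0.9)$verdict, "vus")
})
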