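test_that("the three-class generator plants the documented structure", {
  d <- generate_sp_dataset(100, generator_config(seed = 201))
  expect_equal(nrow(d), 300)
  expect_equal(as.integer(table(d$label)[sp_label_levels]), rep(100L, 3))

  # every SP record has small residues at -1 and -3 of its C-region
  sp <- d[d$label == "SP", ]
  small <- aa_groups()$small
  bounds <- regmatches(sp$description,
                       regexpr("c=[0-9]+-[0-9]+", sp$description))
  c_end <- as.integer(sub(".*-", "", bounds))
  for (i in seq_len(nrow(sp))) {
    expect_true(substr(sp$sequence[i], c_end[i], c_end[i]) %in% small)
    expect_true(substr(sp$sequence[i], c_end[i] - 2, c_end[i] - 2) %in% small)
  }

  # TM stretch lies inside the first 70 residues
  tm <- d[d$label == "TM70", ]
  tm_bounds <- regmatches(tm$description,
                          regexpr("tm=[0-9]+-[0-9]+", tm$description))
  tm_end <- as.integer(sub(".*-", "", tm_bounds))
  expect_true(all(tm_end <= 70))
})

test_that("planted H-regions are enriched in hydrophobic residues", {
  cfg <- generator_config(seed = 202)
  d <- generate_sp_dataset(nrow_cap <- 150, cfg)
  groups <- aa_groups()
  sp <- d[d$label == "SP", ]
  h_bounds <- regmatches(sp$description,
                         regexpr("h=[0-9]+-[0-9]+", sp$description))
  h_freq <- vapply(seq_len(nrow(sp)), function(i) {
    b <- as.integer(strsplit(sub("h=", "", h_bounds[i]), "-")[[1]])
    group_frequency(substr(sp$sequence[i], b[1], b[2]), groups$hydrophobic)
  }, numeric(1))
  incell <- d[d$label == "IN_CELL", ]
  bg_freq <- vapply(n_terminal_window(incell$sequence, 70), group_frequency,
                    numeric(1), group = groups$hydrophobic)
  expect_gt(mean(h_freq), mean(bg_freq))
  expect_equal(mean(h_freq), 1) # H-region drawn from the hydrophobic set
})

test_that("UPS positives are arginine-enriched and lighter", {
  d <- generate_ups_dataset(200, 200, generator_config(seed = 203))
  f <- generate_features(d)
  is_pos <- d$label == "UPS"
  tt <- stats::t.test(f$comp_R[is_pos], f$comp_R[!is_pos])
  expect_gt(unname(tt$statistic), 5)
  expect_lt(mean(f$mol_weight[is_pos]), mean(f$mol_weight[!is_pos]))
  # imbalance geometry option
  imb <- generate_ups_dataset(96, 345, generator_config(seed = 203))
  expect_equal(sum(imb$label == "UPS"), 96L)
  expect_equal(sum(imb$label == "INTRACELLULAR"), 345L)
})

test_that("unit effect multipliers remove all separability", {
  cfg <- generator_config(seed = 204, arginine_multiplier = 1,
                          pos_charge_multiplier = 1, length_factor = 1)
  d <- generate_ups_dataset(500, 500, cfg)
  f <- ups_feature_subset(generate_features(d))
  y01 <- as.integer(d$label == "UPS")
  aucs <- vapply(ups_feature_names(), function(nm) {
    roc_auc(f[[nm]], y01)
  }, numeric(1))
  expect_true(all(abs(aucs - 0.5) < 0.05))
})

test_that("the arginine effect dial is monotone in separability", {
  aucs <- vapply(c(1.5, 2.5, 4), function(mult) {
    cfg <- generator_config(seed = 205, arginine_multiplier = mult)
    d <- generate_ups_dataset(150, 150, cfg)
    f <- generate_features(d)
    roc_auc(f$comp_R, as.integer(d$label == "UPS"))
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("generation is deterministic under seed and strict-valid", {
  cfg <- generator_config(seed = 206)
  expect_identical(generate_sp_dataset(30, cfg), generate_sp_dataset(30, cfg))
  expect_identical(generate_ups_dataset(20, 20, cfg),
                   generate_ups_dataset(20, 20, cfg))
  d1 <- generate_sp_dataset(30, generator_config(seed = 206))
  d2 <- generate_sp_dataset(30, generator_config(seed = 207))
  expect_false(identical(d1$sequence, d2$sequence))
  expect_silent(validate_sequences(d1, "strict"))
})

test_that("drifted copies shift only the requested feature", {
  # homogeneous background set: feature sigma reflects sampling noise,
  # not a planted class effect
  cfg0 <- generator_config(seed = 208, arginine_multiplier = 1,
                           pos_charge_multiplier = 1, length_factor = 1)
  d <- generate_ups_dataset(80, 80, cfg0)
  f0 <- generate_features(d)
  same <- generate_drifted_copy(d, "comp_R", shift = 0, seed = 1)
  expect_identical(same$sequence, d$sequence)

  drifted <- generate_drifted_copy(d, "comp_R", shift = 5, seed = 1)
  f1 <- generate_features(drifted)
  sds <- vapply(f0[, -1], stats::sd, numeric(1))
  moved <- abs(colMeans(f1[, -1]) - colMeans(f0[, -1])) / sds
  expect_gt(moved["comp_R"], 3)
  # isolation: other compositions move less than half a sigma
  others <- setdiff(paste0("comp_", aa_alphabet), "comp_R")
  expect_true(all(moved[others] < 0.5))

  expect_error(generate_drifted_copy(d, "not_a_feature", 5, 1), "Unknown")
})

test_that("fasta and label output round trips through sequence io", {
  d <- generate_sp_dataset(10, generator_config(seed = 209))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(d, fa)
  write_label_table(d, tsv)
  back <- read_label_table(tsv, read_fasta(fa), task = "sp")
  expect_equal(nrow(back), 30)
  expect_equal(as.character(back$label), d$label[match(back$id, d$id)])
})
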