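test_that("proteome generation is deterministic and respects invariants", {
  p1 <- generate_proteome(n_per_group = c(cytoplasmome = 50, secretome = 50),
                          seed = 5)
  p2 <- generate_proteome(n_per_group = c(cytoplasmome = 50, secretome = 50),
                          seed = 5)
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))

  expect_length(p1$records, 100)
  for (r in p1$records) {
    expect_gt(nchar(r$sequence), 0)
    expect_lt(r$sp_length, nchar(r$sequence))
    expect_true(r$topology_class %in% c("A", "N", "F1", "r", "G", "H", "I", "X"))
  }
  sp <- vapply(p1$records, `[[`, 0L, "sp_length")
  expect_true(all(sp[p1$truth$group == "secretome"] > 0))
  expect_true(all(sp[p1$truth$group == "cytoplasmome"] == 0))

  bad <- default_composition_targets()
  bad$secretome["A"] <- bad$secretome["A"] + 0.1
  expect_error(generate_proteome(composition = bad, seed = 1), "sum to 1")
})

test_that("realized group compositions land within 0.01 of the targets", {
  p <- generate_proteome(n_per_group = c(cytoplasmome = 500, secretome = 500),
                         seed = 17)
  tg <- p$truth$composition_targets
  sets <- residue_sets()
  for (g in c("cytoplasmome", "secretome")) {
    accs <- names(p$truth$group)[p$truth$group == g]
    fr <- vapply(accs, function(a) {
      unname(composition_profile(mature_sequence(p$records[[a]]))["polar"])
    }, numeric(1))
    target <- sum(tg[[g]][intersect(names(tg[[g]]), sets$polar)])
    expect_lt(abs(mean(fr) - target), 0.01)
  }
})

test_that("track generation plants recoverable plateaus and flags overlaps", {
  tr <- generate_track_with_segments(100, baseline = 0.2, noise_sd = 0.05,
                                     threshold = 0.5,
                                     planted = data.frame(start = 20, end = 40),
                                     snr = 3, seed = 2)
  expect_length(tr, 100)
  seg <- extract_segments(tr, 0.5, 5)
  expect_equal(nrow(seg), 1)
  ov <- length(intersect(seg$start[1]:seg$end[1], 20:40))
  expect_gte(ov / max(seg$length[1], 21), 0.9)   # reciprocal overlap

  expect_error(generate_track_with_segments(
    100, 0.2, 0.05, 0.5,
    planted = data.frame(start = c(10, 15), end = c(20, 30))), "overlapping")
  expect_error(generate_track_with_segments(100, 0.6, 0.05, 0.5), "baseline")
})

test_that("unplanted tracks rarely produce false segments at a high threshold", {
  set.seed(3)
  fp <- vapply(1:500, function(i) {
    tr <- generate_track_with_segments(200, baseline = 0.2, noise_sd = 0.05,
                                       threshold = 0.5)
    nrow(extract_segments(tr, 0.5, 5)) > 0
  }, logical(1))
  expect_gte(mean(!fp), 0.95)
})

test_that("toy structures order rCO as hairpin > helix > extended floor", {
  h <- generate_toy_structure("helix", 40)
  e <- generate_toy_structure("extended", 40)
  hp <- generate_toy_structure("hairpin", 40)
  expect_equal(length(h$resolved), 40)
  rco <- function(m) relative_contact_order(m, cutoff = 6, ca_only = TRUE)$rco
  expect_equal(rco(e), 1 / 40)
  expect_gt(rco(hp), rco(h))
  ## helix contacts are short-range: i+3 within reach, i+4 beyond 6 A
  cp <- contact_pairs(h, cutoff = 6, ca_only = TRUE)
  expect_lte(max(cp$j - cp$i), 4)
  expect_error(generate_toy_structure("helix", 2), "length")
})

test_that("fold tables recover the planted design exactly", {
  accs <- list(cytoplasmome = sprintf("c%03d", 1:60),
               secretome = sprintf("s%03d", 1:40))
  design <- default_fold_design()
  ft <- generate_fold_table(design, accs, seed = 4)
  groups <- setNames(rep(c("cytoplasmome", "secretome"), c(60, 40)),
                     c(accs$cytoplasmome, accs$secretome))
  cen <- fold_census(ft, groups)
  f <- cen$folds
  ## per-fold per-group counts match the design
  m <- merge(design, f, by = "fold_id")
  expect_equal(m$cytoplasmome, m$n_cytoplasmome)
  expect_equal(m$secretome, m$n_secretome)
  ## the five planted unique secretome folds are unique, beta-dominated
  us <- f[grepl("^us", f$fold_id), ]
  expect_equal(nrow(us), 5)
  expect_true(all(us$status == "unique"))
  expect_equal(sum(us$scop_class == "b"), 4)

  bad <- design; bad$n_cytoplasmome[1] <- 0L; bad$n_secretome[1] <- 0L
  expect_error(generate_fold_table(bad, accs, seed = 1), "zero proteins")
})

test_that("abundance generation realizes the planted variability classes", {
  g <- generate_abundance(sprintf("p%03d", 1:300), seed = 6)
  expect_equal(dim(g$abundance), c(300, 13))
  expect_true(all(g$abundance > 0))
  vs <- variability_score(g$abundance)
  ## constant class rows have VS exactly zero
  expect_true(all(vs[g$classes == "very_low"] == 0))
  ## planted class ordering is realized in the medians
  med <- tapply(vs, g$classes, median)
  expect_true(all(diff(med) > 0))

  g2 <- generate_abundance(sprintf("p%03d", 1:300), seed = 6)
  expect_identical(g$abundance, g2$abundance)
})

test_that("study generation is deterministic and carries coherent truth", {
  s1 <- generate_synthetic_study(n_per_group = 30, seed = 12)
  s2 <- generate_synthetic_study(n_per_group = 30, seed = 12)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  expect_length(s1$bundle$records, 60)
  ## tracks align with mature lengths
  for (a in names(s1$bundle$records)[c(1, 15, 40)]) {
    L <- nchar(mature_sequence(s1$bundle$records[[a]]))
    expect_length(s1$bundle$tracks$disorder[[a]], L)
    expect_length(s1$bundle$tracks$aggregation[[a]], L)
  }
  ## planted segments stay within bounds
  for (a in names(s1$truth$planted$disorder)) {
    seg <- s1$truth$planted$disorder[[a]]
    if (nrow(seg)) {
      L <- nchar(mature_sequence(s1$bundle$records[[a]]))
      expect_true(all(seg$start >= 1 & seg$end <= L))
    }
  }
  ## effect ledger covers both directions
  expect_setequal(unique(s1$truth$effects$higher),
                  c("cytoplasmome", "secretome"))
})

test_that("planted gatekeeper bias is visible in called gatekeeper composition", {
  st <- generate_synthetic_study(
    n_per_group = 40, seed = 9,
    config = list(gatekeeper_bias = list(
      cytoplasmome = c(P = 0.5, R = 0.5),
      secretome = c(P = 0.5, R = 0.5))))
  comp_tot <- setNames(numeric(21), c(names(kyte_doolittle()), "X"))
  n <- 0
  for (a in names(st$bundle$records)) {
    ap <- apr_gatekeepers(st$bundle$tracks$aggregation[[a]],
                          mature_sequence(st$bundle$records[[a]]))
    k <- length(ap$gatekeeper_positions)
    if (k) {
      comp_tot[names(ap$composition)] <-
        comp_tot[names(ap$composition)] + ap$composition * k
      n <- n + k
    }
  }
  comp <- comp_tot / n
  expect_gt(comp[["P"]] + comp[["R"]], 0.8)
})
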