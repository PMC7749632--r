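make_ext_scenario <- function(p3 = "diol", t_start = 6) {
  templ <- "ACGUACGUACGU"
  primer <- reverse_complement(substr(templ, t_start + 1, t_start + 4))
  make_scenario(c(templ, primer),
                data.frame(templ = 1, oligo = 2, t_start = t_start,
                           o_start = 0, len = 4),
                p3 = c("diol", p3))
}

test_that("templated extension conserves mass and copies the template", {
  sc <- make_ext_scenario()
  rp <- reaction_params(p_ext = 1, eps = 0, p_ara = 0)
  sites <- classify_sites(sc$config, sc$pool, rp)
  site <- sites[sites$kind == "extension" & sites$role == "oligo", ][1, ]
  before <- total_units(sc$pool)
  res <- extend_primer(site, sc$config, sc$pool, rp, seed = 1)
  expect_true(res$fired)
  expect_equal(total_units(res$pool), before)
  # the grown primer is still a perfect reverse complement of its template
  grown <- res$config$mol$seq[2]
  expect_gt(nchar(grown), 4)
  g <- vcg_genome("ACGUACGUACGU")
  expect_gt(nrow(map_oligo(g, grown)), 0)
  # substrate accounting: bridged dinucleotides consumed, one activated
  # monomer released per incorporation
  n_added <- nchar(grown) - 4
  expect_equal(sum(sc$pool$fed$bridged) - sum(res$pool$fed$bridged),
               n_added)
  expect_equal(sum(res$pool$fed$monomers) - sum(sc$pool$fed$monomers),
               n_added)
})

test_that("extension is processive down an open template overhang", {
  sc <- make_ext_scenario()
  rp <- reaction_params(p_ext = 1, f_last = 1, eps = 0)
  sites <- classify_sites(sc$config, sc$pool, rp)
  site <- sites[sites$kind == "extension" & sites$role == "oligo", ][1, ]
  res <- extend_primer(site, sc$config, sc$pool, rp, seed = 2)
  # with certain firing the primer copies the whole overhang
  expect_equal(nchar(res$config$mol$seq[2]), 10)
  expect_equal(res$config$mol$seq[2],
               reverse_complement(substr("ACGUACGUACGU", 1, 10)))
})

test_that("last-base sites obey the f_last slowdown", {
  sc <- make_ext_scenario(t_start = 1)
  rp <- reaction_params(p_ext = 1, f_last = 0)
  sites <- classify_sites(sc$config, sc$pool, rp)
  site <- sites[sites$kind == "extension", ][1, ]
  expect_true(site$last_base)
  for (s in 1:50) {
    res <- extend_primer(site, sc$config, sc$pool, rp, seed = s)
    expect_false(res$fired)
  }
})

test_that("wrong bases are incorporated at the configured error rate", {
  sc <- make_ext_scenario()
  rp <- reaction_params(p_ext = 1, eps = 0.01, p_ara = 0,
                        p_stall_after_mismatch = 0)
  sites <- classify_sites(sc$config, sc$pool, rp)
  site <- sites[sites$kind == "extension" & sites$role == "oligo", ][1, ]
  correct <- reverse_complement(substr("ACGUACGUACGU", 6, 6))
  n <- 1e4
  wrong <- 0
  set.seed(11)
  for (i in seq_len(n)) {
    res <- extend_primer(site, sc$config, sc$pool, rp)
    added <- substr(res$config$mol$seq[2], 5, 5)
    if (added != correct) wrong <- wrong + 1
    if (added != correct) expect_true(res$config$mol$stalled[2])
  }
  sigma <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(wrong / n - 0.01), 3 * sigma)
})

test_that("chain terminators block all further extension", {
  sc <- make_ext_scenario()
  rp <- reaction_params(p_ext = 1, p_ara = 1)
  sites <- classify_sites(sc$config, sc$pool, rp)
  site <- sites[sites$kind == "extension" & sites$role == "oligo", ][1, ]
  res <- extend_primer(site, sc$config, sc$pool, rp, seed = 3)
  expect_true(res$fired)
  expect_equal(nchar(res$config$mol$seq[2]), 5)  # exactly one addition
  expect_equal(res$config$mol$p3[2], "blocked_terminator")
  s2 <- classify_sites(res$config, res$pool, rp)
  expect_equal(sum(s2$kind == "extension" & s2$primer == 2), 0)
})

test_that("ligation merges adjacent genome fragments into one mappable oligo", {
  templ <- "ACGUACGUACGU"
  primer <- reverse_complement(substr(templ, 7, 10))
  down <- reverse_complement(substr(templ, 1, 6))
  sc <- make_scenario(c(templ, primer, down),
                      data.frame(templ = c(1, 1), oligo = c(2, 3),
                                 t_start = c(6, 0), o_start = c(0, 0),
                                 len = c(4, 6)),
                      p5 = c("phosphate", "phosphate", "activated_2AI"))
  rp <- reaction_params(p_lig = 1)
  sites <- classify_sites(sc$config, sc$pool, rp)
  site <- sites[sites$kind == "ligation", ][1, ]
  before <- total_units(sc$pool)
  res <- ligate(site, sc$config, sc$pool, rp, seed = 4)
  expect_true(res$fired)
  expect_equal(total_units(res$pool), before)
  product <- res$config$mol$seq[res$config$mol$seq != templ]
  expect_equal(product, paste0(primer, down))
  expect_gt(nrow(map_oligo(vcg_genome(templ), product)), 0)
  # product inherits the upstream 5' and downstream 3' states
  prow <- which(res$config$mol$seq == product)
  expect_equal(res$config$mol$p5[prow], "phosphate")
  expect_equal(res$config$mol$p3[prow], "diol")
  expect_equal(res$pool$ledger$lig_leaving, 1)

  # p_lig = 0 leaves the pool unchanged
  res0 <- ligate(site, sc$config, sc$pool, reaction_params(p_lig = 0),
                 seed = 4)
  expect_false(res0$fired)
  expect_equal(res0$pool$species, sc$pool$species)
})

test_that("initiation seeds a templated trinucleotide from two dinucleotides", {
  templ <- "ACGUACGU"
  sc <- make_scenario(templ, data.frame(templ = integer(),
                                        oligo = integer(),
                                        t_start = integer(),
                                        o_start = integer(),
                                        len = integer()))
  rp <- reaction_params(p_init = 1)
  sites <- classify_sites(sc$config, sc$pool, rp)
  site <- sites[sites$kind == "initiation", ][1, ]
  before <- total_units(sc$pool)
  res <- initiate(site, sc$config, sc$pool, rp, seed = 5)
  expect_true(res$fired)
  expect_equal(total_units(res$pool), before)
  tri <- res$config$mol$seq[nchar(res$config$mol$seq) == 3]
  expect_equal(nchar(tri), 3)
  expect_gt(nrow(map_oligo(vcg_genome(templ), tri)), 0)
  # two bridged dinucleotides consumed, one activated monomer released
  expect_equal(sum(sc$pool$fed$bridged) - sum(res$pool$fed$bridged), 2)
  expect_equal(sum(res$pool$fed$monomers) - sum(sc$pool$fed$monomers), 1)
})

test_that("initiation products carry activated or plain 5' ends evenly", {
  templ <- "ACGUACGU"
  sc <- make_scenario(templ, data.frame(templ = integer(),
                                        oligo = integer(),
                                        t_start = integer(),
                                        o_start = integer(),
                                        len = integer()))
  rp <- reaction_params(p_init = 1)
  sites <- classify_sites(sc$config, sc$pool, rp)
  site <- sites[sites$kind == "initiation", ][1, ]
  n <- 1000
  act <- 0
  set.seed(21)
  for (i in seq_len(n)) {
    res <- initiate(site, sc$config, sc$pool, rp)
    p5 <- res$config$mol$p5[nchar(res$config$mol$seq) == 3]
    act <- act + (p5 == "activated_2AI")
  }
  expect_lt(abs(act / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("activation turnover reaches the two-state stationary fraction", {
  pool <- make_pool(rep("AAAA", 1), count = 2000,
                    p5 = "phosphate")
  rp0 <- reaction_params(k_hyd = 0, k_act = 0)
  expect_equal(update_activation(pool, rp0, seed = 1)$species,
               pool$species)
  rp <- reaction_params(k_hyd = 0.1, k_act = 0.1)
  p <- pool
  set.seed(6)
  for (i in 1:60) p <- update_activation(p, rp)
  frac <- sum(p$species$count[p$species$p5 == "activated_2AI"]) /
    sum(p$species$count)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
  # pure hydrolysis decays the activated fraction as (1 - k_hyd)^t
  pa <- make_pool("AAAA", count = 4000, p5 = "activated_2AI")
  rph <- reaction_params(k_hyd = 0.2, k_act = 0)
  set.seed(8)
  for (i in 1:5) pa <- update_activation(pa, rph)
  frac5 <- sum(pa$species$count[pa$species$p5 == "activated_2AI"]) / 4000
  expected <- 0.8^5
  expect_lt(abs(frac5 - expected),
            3 * sqrt(expected * (1 - expected) / 4000))
})

test_that("cleavage assigns the canonical end fates", {
  # phosphodiester cleavage: 5'-hydroxyl downstream, cyclic phosphate up
  dimer <- make_pool("AC", count = 1, p5 = "activated_2AI")
  rp <- reaction_params(p_cleave = 1, h_cp = 0)
  cut <- cleave_strands(dimer, rp, seed = 1)
  expect_equal(sort(cut$species$seq), c("A", "C"))
  up <- cut$species[cut$species$seq == "A", ]
  dn <- cut$species[cut$species$seq == "C", ]
  expect_equal(up$p3, "cyclic_phosphate")
  expect_equal(up$p5, "activated_2AI")
  expect_equal(dn$p5, "hydroxyl")
  expect_equal(dn$p3, "diol")

  # pyrophosphate linkage: downstream keeps a ligatable 5'-phosphate
  pp_pool <- vcg_pool(data.frame(seq = "ACGUACGUAC", p5 = "phosphate",
                                 p3 = "diol", stalled = FALSE, pp = "4",
                                 count = 1, stringsAsFactors = FALSE),
                      volume = 1e-15)
  rpp <- reaction_params(p_cleave = 0, p_pp = 1, h_cp = 0)
  cut2 <- cleave_strands(pp_pool, rpp, seed = 2)
  expect_setequal(cut2$species$seq, c("ACGU", "ACGUAC"))
  expect_equal(cut2$species$p3[cut2$species$seq == "ACGU"],
               "cyclic_phosphate")
  expect_equal(cut2$species$p5[cut2$species$seq == "ACGUAC"],
               "phosphate")

  # identity when nothing cleaves
  same <- cleave_strands(pp_pool, reaction_params(p_cleave = 0, p_pp = 0),
                         seed = 3)
  expect_equal(same$species, pp_pool$species)
})

test_that("cyclic phosphate termini hydrolyse to 2'- or 3'-phosphates", {
  pool <- make_pool("ACGU", count = 4000, p3 = "cyclic_phosphate")
  rp <- reaction_params(p_cleave = 0, p_pp = 0, h_cp = 1)
  out <- cleave_strands(pool, rp, seed = 9)
  sp <- out$species
  expect_setequal(unique(sp$p3), c("phosphate_2p", "phosphate_3p"))
  f2 <- sum(sp$count[sp$p3 == "phosphate_2p"]) / 4000
  expect_lt(abs(f2 - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("cleavage fragment counts follow 1 + (N-1) p", {
  n <- 1e4
  pool <- make_pool("ACGUACGUAC", count = n)  # 10-mers, 9 bonds
  p <- 0.01
  out <- cleave_strands(pool, reaction_params(p_cleave = p, p_pp = 0,
                                              h_cp = 0), seed = 12)
  frags_per_mol <- sum(out$species$count) / n
  expected <- 1 + 9 * p
  sigma <- sqrt(9 * p * (1 - p) / n)
  expect_lt(abs(frags_per_mol - expected), 3 * sigma)
})

test_that("a quiescent cycle leaves the pool composition unchanged", {
  g <- generate_fixture_genome(16, seed = 5)
  rp <- reaction_params(p_ext = 0, p_lig = 0, p_init = 0, p_cleave = 0,
                        p_cyc = 0, k_hyd = 0, k_act = 0, p_invade = 0,
                        h_cp = 0, p_pp = 0, dead_end_len = 99,
                        monomer_feed = 0, bridged_feed = 0)
  pool <- init_gradient_pool(g, volume = protocell_volume(5e-8),
                             reaction = rp, seed = 4)
  st <- protocell_state(pool, g)
  st2 <- step_cycle(st, sim_params(reaction = rp), seed = 5)
  key <- function(sp) sp[order(sp$seq, sp$p5, sp$p3), ]
  a <- key(st$pool$species); b <- key(st2$pool$species)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("the nucleotide ledger balances across seeded cycles", {
  g <- generate_fixture_genome(16, seed = 6)
  pool <- init_gradient_pool(g, volume = protocell_volume(5e-8), seed = 7)
  st <- protocell_state(pool, g)
  p <- sim_params()
  base <- ledger_balance(st)
  set.seed(31)
  for (i in 1:30) {
    st <- step_cycle(st, p)
    expect_equal(ledger_balance(st), base)
  }
})

test_that("per-base stalling throttles extension after a mismatch", {
  sc <- make_ext_scenario()
  sc$config$mol$stalled[2] <- TRUE
  rp <- reaction_params(p_ext = 1, p_stall_after_mismatch = 0, eps = 0)
  sites <- classify_sites(sc$config, sc$pool, rp)
  site <- sites[sites$kind == "extension" & sites$role == "oligo", ][1, ]
  res <- extend_primer(site, sc$config, sc$pool, rp, seed = 2)
  expect_false(res$fired)  # fully stalled primer cannot move
  rp2 <- reaction_params(p_ext = 1, p_stall_after_mismatch = 1, eps = 0)
  res2 <- extend_primer(site, sc$config, sc$pool, rp2, seed = 2)
  expect_true(res2$fired)
  # one successful templated addition clears the stall
  expect_false(res2$config$mol$stalled[2])
})
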