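test_that("duplex energy is the per-pair sum over the matched overlap", {
  ep <- energy_params()  # -2.5 kcal/mol per pair
  a <- strrep("A", 10)
  expect_equal(duplex_energy(a, strrep("U", 10), 0, ep), -25)
  expect_equal(duplex_energy("ACG", "GGGGG", 40, ep), 0)  # no overlap
  # mismatches contribute nothing
  expect_equal(duplex_energy("AAG", "UUU", 0, ep), -5)
  # pair modifiers scale specific pair types
  epi <- energy_params(pair_modifiers = c(AU = 1, GC = 1, IC = 0.6))
  expect_equal(duplex_energy("II", "CC", 0, epi, alphabet = "ACIU"),
               2 * -2.5 * 0.6)
  # the free-energy equivalent of a twofold concentration change
  ep298 <- energy_params(temperature = 298)
  expect_equal(rt_energy(ep298) * log(2), 0.41047, tolerance = 1e-4)
})

test_that("complementary strands pair and unrelated strands stay free", {
  a <- "ACGUACGU"
  pool <- make_pool(c(a, reverse_complement(a)), volume = 1e-18)
  for (s in 1:25) {
    cfg <- anneal(pool, energy_params(), seed = s)
    expect_equal(nrow(cfg$bindings), 1)
    expect_equal(cfg$bindings$len, 8)
  }
  inert <- make_pool(c("AAAAA", "AAAAA", "CCCCC"), volume = 1e-18)
  cfg <- anneal(inert, energy_params(), seed = 1)
  expect_equal(nrow(cfg$bindings), 0)
  expect_true(all(cfg$unbound))
})

test_that("competing binders occupy a template at Boltzmann frequencies", {
  templ <- "AAAAAAGGAGGA"
  primer <- reverse_complement(substr(templ, 7, 12))   # 6 bp
  comp <- reverse_complement(substr(templ, 8, 12))     # 5 bp, same half
  ep <- energy_params(dG_bp = -1.2, dG_assoc = 0)
  pool <- make_pool(c(templ, primer, comp), volume = 1e-15)
  ip <- match(primer, pool$species$seq)
  it <- match(templ, pool$species$seq)
  w_p <- exp(6 * 1.2 / rt_energy(ep))
  w_c <- exp(5 * 1.2 / rt_energy(ep))
  n <- 2000
  p_bound <- 0
  set.seed(7)
  for (s in seq_len(n)) {
    cfg <- anneal(pool, ep)
    bound <- cfg$bindings
    is_p <- any((bound$oligo == ip & bound$templ == it) |
                  (bound$oligo == it & bound$templ == ip))
    p_bound <- p_bound + is_p
  }
  expected <- w_p / (w_p + w_c)
  sigma <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(p_bound / n - expected), 3 * sigma)
})

test_that("annealed configurations never claim a template position twice", {
  g <- generate_fixture_genome(16, seed = 4)
  pool <- init_gradient_pool(g, volume = protocell_volume(5e-8), seed = 2)
  for (s in 1:20) {
    cfg <- anneal(pool, sim_params(), seed = s)
    b <- cfg$bindings
    for (t in unique(b$templ)) {
      rows <- b[b$templ == t, ]
      pos <- unlist(lapply(seq_len(nrow(rows)), function(i)
        rows$t_start[i] + seq_len(rows$len[i]) - 1))
      expect_equal(anyDuplicated(pos), 0)
      expect_true(all(rows$len >= 2))
    }
    # role exclusivity: a bound oligo is not simultaneously a template
    expect_length(intersect(b$oligo, b$templ), 0)
  }
})

test_that("stronger pairing never decreases the expected bound count", {
  g <- generate_fixture_genome(16, seed = 9)
  pool <- init_gradient_pool(g, volume = protocell_volume(4e-8), seed = 3)
  mean_bound <- function(dg) {
    tot <- 0
    for (s in 1:30)
      tot <- tot + nrow(anneal(pool, energy_params(dG_bp = dg),
                               seed = s)$bindings)
    tot / 30
  }
  weak <- mean_bound(-1)
  strong <- mean_bound(-3)
  expect_gte(strong, weak)
})

test_that("site classification separates the productive geometries", {
  templ <- "ACGUACGUACGU"
  primer <- reverse_complement(substr(templ, 7, 10))  # 3' end at pos 6
  sc <- make_scenario(c(templ, primer),
                      data.frame(templ = 1, oligo = 2, t_start = 6,
                                 o_start = 0, len = 4))
  sites <- classify_sites(sc$config, sc$pool, reaction_params())
  ext <- sites[sites$kind == "extension" & sites$role == "oligo", ]
  expect_equal(nrow(ext), 1)
  expect_equal(ext$overhang, 6)
  expect_false(ext$last_base)
  expect_equal(ext$t_next, 5)

  # one-nucleotide overhang: the bridged dinucleotide can pair only one
  # base and the site is flagged last_base
  primer1 <- reverse_complement(substr(templ, 2, 6))
  sc1 <- make_scenario(c(templ, primer1),
                       data.frame(templ = 1, oligo = 2, t_start = 1,
                                  o_start = 0, len = 5))
  s1 <- classify_sites(sc1$config, sc1$pool, reaction_params())
  e1 <- s1[s1$kind == "extension" & s1$role == "oligo", ]
  expect_true(e1$last_base)
  expect_equal(e1$overhang, 1)

  # a 5'-activated oligo bound flush downstream makes a ligation site
  down <- reverse_complement(substr(templ, 1, 6))
  sc2 <- make_scenario(c(templ, primer, down),
                       data.frame(templ = c(1, 1), oligo = c(2, 3),
                                  t_start = c(6, 0), o_start = c(0, 0),
                                  len = c(4, 6)),
                       p5 = c("phosphate", "phosphate", "activated_2AI"))
  s2 <- classify_sites(sc2$config, sc2$pool, reaction_params())
  expect_equal(sum(s2$kind == "ligation"), 1)
  expect_equal(s2$down_binding[s2$kind == "ligation"], 2)

  # a 5'-hydroxyl downstream cannot ligate: cleavage products lacking the
  # phosphate never rejoin upstream oligos
  sc3 <- make_scenario(c(templ, primer, down),
                       data.frame(templ = c(1, 1), oligo = c(2, 3),
                                  t_start = c(6, 0), o_start = c(0, 0),
                                  len = c(4, 6)),
                       p5 = c("phosphate", "phosphate", "hydroxyl"))
  s3 <- classify_sites(sc3$config, sc3$pool, reaction_params())
  expect_equal(sum(s3$kind == "ligation"), 0)
  expect_true(any(s3$kind == "blocked" & s3$primer == 2))

  # blocked 3' chemistry blocks extension
  sc4 <- make_scenario(c(templ, primer),
                       data.frame(templ = 1, oligo = 2, t_start = 6,
                                  o_start = 0, len = 4),
                       p3 = c("diol", "cyclic_phosphate"))
  s4 <- classify_sites(sc4$config, sc4$pool, reaction_params())
  expect_equal(sum(s4$kind == "extension" & s4$role == "oligo"), 0)
})

test_that("initiation sites need an open stretch and both dinucleotides", {
  templ <- "ACGUACGU"
  sc <- make_scenario(templ, data.frame(templ = integer(),
                                        oligo = integer(),
                                        t_start = integer(),
                                        o_start = integer(),
                                        len = integer()))
  sites <- classify_sites(sc$config, sc$pool, reaction_params())
  expect_true(any(sites$kind == "initiation"))
  # no bridged dinucleotides in stock: no initiation anywhere
  sc$pool$fed$bridged[] <- 0
  s0 <- classify_sites(sc$config, sc$pool, reaction_params())
  expect_equal(sum(s0$kind == "initiation"), 0)
})

test_that("toehold invasion opens occluded templates", {
  # template's downstream positions occluded by a strand with a free
  # 5' tail; a complementary invader displaces it (Fig-style scenario)
  templ <- "ACGUACGUACGU"
  primer <- reverse_complement(substr(templ, 7, 10))  # needs pos 6 free
  occluder <- paste0("GGGG", reverse_complement(substr(templ, 1, 7)))
  invader <- reverse_complement("GGGG")
  seqs <- c(templ, primer, occluder, invader)
  bind <- data.frame(templ = c(1, 1), oligo = c(2, 3),
                     t_start = c(6, 0), o_start = c(0, 4),
                     len = c(4, 7))
  sc <- make_scenario(seqs, bind)
  rp1 <- reaction_params(p_invade = 1, toehold_min = 3)
  before <- classify_sites(sc$config, sc$pool, rp1)
  expect_true(any(before$kind == "blocked" & before$primer == 2))

  opened <- invasion_open(sc$config, sc$pool, rp1, seed = 1)
  after <- classify_sites(opened, sc$pool, rp1)
  expect_true(any(after$kind == "extension" & after$primer == 2))
  # the occluding strand is now annealed onto the invader
  expect_true(any(after$templ == 3 | opened$bindings$templ == 3))

  # p_invade = 0 is the identity
  rp0 <- reaction_params(p_invade = 0)
  same <- invasion_open(sc$config, sc$pool, rp0, seed = 1)
  expect_equal(same$bindings, sc$config$bindings)

  # without an invader in the pool nothing changes
  sc2 <- make_scenario(seqs[1:3], bind)
  same2 <- invasion_open(sc2$config, sc2$pool, rp1, seed = 1)
  expect_equal(same2$bindings, sc2$config$bindings)
})
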