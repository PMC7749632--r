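# --- internal firing context -------------------------------------------------
# During the reaction phase of a cycle the molecule table, bindings, template
# coverage, fed species and ledger live in one mutable environment so the
# per-site reactions can update them in place.

make_fire_ctx <- function(config, pool) {
  ctx <- new.env(parent = emptyenv())
  ctx$mol <- config$mol
  ctx$alive <- rep(TRUE, nrow(config$mol))
  ctx$bindings <- config$bindings
  ctx$bind_alive <- rep(TRUE, nrow(config$bindings))
  ctx$cov <- coverage_masks(config)
  ctx$fed <- pool$fed
  ctx$ledger <- pool$ledger
  ctx$alphabet <- config$alphabet
  ctx$events <- c(extension = 0, ligation = 0, initiation = 0,
                  mismatch = 0, terminated = 0)
  ctx
}

ctx_to_config <- function(ctx) {
  keep <- which(ctx$alive)
  remap <- match(seq_along(ctx$alive), keep)
  b <- ctx$bindings[ctx$bind_alive, , drop = FALSE]
  b$templ <- remap[b$templ]
  b$oligo <- remap[b$oligo]
  b <- b[!is.na(b$templ) & !is.na(b$oligo), , drop = FALSE]
  rownames(b) <- NULL
  mol <- ctx$mol[keep, , drop = FALSE]
  rownames(mol) <- NULL
  unbound <- !(seq_len(nrow(mol)) %in% c(b$templ, b$oligo))
  new_duplex_config(mol, b, unbound, ctx$alphabet)
}

ctx_to_pool <- function(ctx, pool) {
  pool$fed <- ctx$fed
  pool$ledger <- ctx$ledger
  compact_molecules(ctx$mol[ctx$alive, , drop = FALSE], pool)
}

parse_pp <- function(pp) {
  if (is.na(pp) || pp == "") integer(0)
  else as.integer(strsplit(pp, ",", fixed = TRUE)[[1]])
}
format_pp <- function(x) if (length(x)) paste(sort(x), collapse = ",") else ""

# single templated incorporation onto primer `o`; returns the added base
incorporate_base <- function(ctx, o, templated, eps) {
  bases <- alphabet_bases(ctx$alphabet)
  base <- templated
  if (eps > 0 && stats::runif(1) < eps) {
    base <- sample(setdiff(bases, templated), 1L)
    ctx$mol$stalled[o] <- TRUE
    ctx$events[["mismatch"]] <- ctx$events[["mismatch"]] + 1
  } else if (ctx$mol$stalled[o]) {
    ctx$mol$stalled[o] <- FALSE  # one further success clears the stall
  }
  base
}

# Extension is processive within a cycle: while the productive
# configuration lasts, successive nucleotides are added (each a Bernoulli
# p_ext trial against a fresh bridged dinucleotide) until a trial fails,
# the template overhang is exhausted, substrate runs out, or a terminator
# is incorporated.
fire_extension <- function(ctx, site, params) {
  o <- site$primer; t <- site$templ; bi <- site$binding
  if (!ctx$alive[o] || !ctx$alive[t] || !ctx$bind_alive[bi]) return(FALSE)
  templ_side <- identical(site$role, "templ")
  comp <- complement_map(ctx$alphabet)
  any_fired <- FALSE
  repeat {
    t_next <- if (templ_side) ctx$bindings$o_start[bi] - 1L
              else ctx$bindings$t_start[bi] - 1L
    if (t_next < 0L || ctx$cov[[t]][t_next + 1L]) break
    if (!extendable_3p(ctx$mol$p3[o])) break
    last_base <- t_next == 0L || ctx$cov[[t]][t_next]
    x <- comp[[substr(ctx$mol$seq[t], t_next + 1L, t_next + 1L)]]
    # substrate: the bridged dinucleotide pairing the next one or two bases
    if (last_base) {
      cand <- ctx$fed$bridged[startsWith(names(ctx$fed$bridged), x)]
      cand <- cand[cand > 0]
      if (!length(cand)) break
      key <- sample(names(cand), 1L, prob = cand)
    } else {
      y <- comp[[substr(ctx$mol$seq[t], t_next, t_next)]]
      key <- paste0(x, y)
      if (ctx$fed$bridged[key] <= 0) break
    }
    p <- params$p_ext
    if (last_base) p <- p * params$f_last
    if (ctx$mol$stalled[o]) p <- p * params$p_stall_after_mismatch
    if (x %in% c("A", "G", "I")) p <- p * params$p_ext_purine_mult
    if (stats::runif(1) > p) break

    old_len <- nchar(ctx$mol$seq[o])
    base <- incorporate_base(ctx, o, x, params$eps)
    ctx$mol$seq[o] <- paste0(ctx$mol$seq[o], base)
    if (ctx$mol$p3[o] == "phosphate_3p")  # extension over a 3'-phosphate
      ctx$mol$pp[o] <- format_pp(c(parse_pp(ctx$mol$pp[o]), old_len))
    terminated <- params$p_ara > 0 && stats::runif(1) < params$p_ara
    ctx$mol$p3[o] <- if (terminated) {
      ctx$events[["terminated"]] <- ctx$events[["terminated"]] + 1
      "blocked_terminator"
    } else "diol"
    ctx$fed$bridged[key] <- ctx$fed$bridged[key] - 1
    lg <- substr(key, 2L, 2L) # leaving group: the distal activated monomer
    ctx$fed$monomers[lg] <- ctx$fed$monomers[lg] + 1
    if (templ_side) ctx$bindings$o_start[bi] <- t_next
    else ctx$bindings$t_start[bi] <- t_next
    ctx$bindings$len[bi] <- ctx$bindings$len[bi] + 1L
    ctx$cov[[t]][t_next + 1L] <- TRUE
    ctx$cov[[o]] <- c(ctx$cov[[o]], TRUE)  # the added base is paired
    ctx$events[["extension"]] <- ctx$events[["extension"]] + 1
    any_fired <- TRUE
    if (terminated) break
  }
  any_fired
}

fire_ligation <- function(ctx, site, params) {
  o <- site$primer; bi <- site$binding; bj <- site$down_binding
  if (!ctx$bind_alive[bi] || !ctx$bind_alive[bj]) return(FALSE)
  j <- ctx$bindings$oligo[bj]
  if (!ctx$alive[o] || !ctx$alive[j]) return(FALSE)
  if (!ligatable_5p(ctx$mol$p5[j])) return(FALSE)
  if (stats::runif(1) > params$p_lig) return(FALSE)
  li <- nchar(ctx$mol$seq[o])
  pp <- c(parse_pp(ctx$mol$pp[o]), parse_pp(ctx$mol$pp[j]) + li)
  if (ctx$mol$p3[o] == "phosphate_3p") pp <- c(pp, li)
  ctx$mol$seq[o] <- paste0(ctx$mol$seq[o], ctx$mol$seq[j])
  ctx$mol$p3[o] <- ctx$mol$p3[j]       # product: upstream 5', downstream 3'
  ctx$mol$stalled[o] <- ctx$mol$stalled[j]
  ctx$mol$pp[o] <- format_pp(pp)
  ctx$alive[j] <- FALSE
  # merge the two contiguous runs into one binding on the primer
  ctx$bindings$t_start[bi] <- ctx$bindings$t_start[bj]
  ctx$bindings$len[bi] <- ctx$bindings$len[bi] + ctx$bindings$len[bj]
  ctx$bind_alive[bj] <- FALSE
  ctx$ledger$lig_leaving <- ctx$ledger$lig_leaving + 1
  ctx$events[["ligation"]] <- ctx$events[["ligation"]] + 1
  TRUE
}

fire_initiation <- function(ctx, site, params) {
  t <- site$templ
  if (!ctx$alive[t]) return(FALSE)
  q <- site$t_next  # 0-based start of the 4-nt window
  if (any(ctx$cov[[t]][(q + 1L):(q + 4L)])) return(FALSE)
  d1 <- site$d1; d2 <- site$d2
  need1 <- if (d1 == d2) 2 else 1
  if (ctx$fed$bridged[d1] < need1 || ctx$fed$bridged[d2] < 1) return(FALSE)
  if (stats::runif(1) > params$p_init) return(FALSE)
  ctx$fed$bridged[d1] <- ctx$fed$bridged[d1] - 1
  ctx$fed$bridged[d2] <- ctx$fed$bridged[d2] - 1
  lg <- substr(d2, 2L, 2L)  # monomer pairing the 4th position leaves
  ctx$fed$monomers[lg] <- ctx$fed$monomers[lg] + 1
  tri <- paste0(d1, substr(d2, 1L, 1L))
  p5 <- if (stats::runif(1) < 0.5) "activated_2AI" else "phosphate"
  ctx$mol <- rbind(ctx$mol,
                   data.frame(seq = tri, p5 = p5, p3 = "diol",
                              stalled = FALSE, pp = "",
                              stringsAsFactors = FALSE))
  ctx$alive <- c(ctx$alive, TRUE)
  new_id <- nrow(ctx$mol)
  ctx$bindings <- rbind(ctx$bindings,
                        data.frame(templ = t, oligo = new_id,
                                   t_start = q + 1L, o_start = 0L,
                                   len = 3L, energy = NA_real_))
  ctx$bind_alive <- c(ctx$bind_alive, TRUE)
  ctx$cov[[t]][(q + 2L):(q + 4L)] <- TRUE
  ctx$events[["initiation"]] <- ctx$events[["initiation"]] + 1
  TRUE
}

fire_one <- function(ctx, site, params) {
  switch(site$kind,
         extension = fire_extension(ctx, site, params),
         ligation = fire_ligation(ctx, site, params),
         initiation = fire_initiation(ctx, site, params),
         FALSE)
}

fire_sites <- function(config, pool, sites, params) {
  ctx <- make_fire_ctx(config, pool)
  if (nrow(sites)) {
    for (si in sample.int(nrow(sites))) {
      fire_one(ctx, as.list(sites[si, , drop = FALSE]), params)
    }
  }
  ctx
}

# --- exported single-site reaction wrappers ---------------------------------

#' Fire a single classified reaction site
#'
#' Execute one extension, ligation or initiation site from
#' [classify_sites()] against a configuration and pool, with the
#' per-reaction Bernoulli probability from `params`. These are the
#' site-level building blocks that [step_cycle()] applies to every site of
#' a cycle; exposing them individually makes single-reaction arithmetic
#' (substrate consumption, leaving groups, end-state bookkeeping, mass
#' conservation) directly testable.
#'
#' @param site one-row data.frame (or list) from [classify_sites()] of the
#'   matching kind.
#' @param config a `vcg_duplex_config`.
#' @param pool a [vcg_pool()].
#' @param params a [reaction_params()] (or [sim_params()]).
#' @param seed optional integer seed.
#' @return list with the updated `config`, `pool`, and `fired` (logical).
#' @export
extend_primer <- function(site, config, pool, params = reaction_params(),
                          seed = NULL) {
  fire_wrapper(site, "extension", config, pool, params, seed)
}

#' @rdname extend_primer
#' @export
ligate <- function(site, config, pool, params = reaction_params(),
                   seed = NULL) {
  fire_wrapper(site, "ligation", config, pool, params, seed)
}

#' @rdname extend_primer
#' @export
initiate <- function(site, config, pool, params = reaction_params(),
                     seed = NULL) {
  fire_wrapper(site, "initiation", config, pool, params, seed)
}

fire_wrapper <- function(site, kind, config, pool, params, seed) {
  if (inherits(params, "vcg_sim_params")) params <- params$reaction
  site <- as.list(site)
  if (!identical(site$kind, kind))
    stop("site is not of kind '", kind, "'")
  if (!is.null(seed)) set.seed(seed)
  ctx <- make_fire_ctx(config, pool)
  fired <- fire_one(ctx, site, params)
  list(config = ctx_to_config(ctx), pool = ctx_to_pool(ctx, pool),
       fired = fired)
}

# --- pool-level fate processes ----------------------------------------------

#' Activation turnover of 5' ends
#'
#' Each 2AI-activated 5' end hydrolyses to a plain phosphate with
#' probability `k_hyd` per cycle; each 5'-phosphate is re-activated (in
#' situ activation chemistry) with probability `k_act`. The stationary
#' activated fraction is `k_act / (k_act + k_hyd)`.
#'
#' @param pool a [vcg_pool()].
#' @param params a [reaction_params()] (or [sim_params()]).
#' @param seed optional integer seed.
#' @return the updated pool.
#' @export
update_activation <- function(pool, params = reaction_params(),
                              seed = NULL) {
  if (inherits(params, "vcg_sim_params")) params <- params$reaction
  if (!is.null(seed)) set.seed(seed)
  mol <- expand_pool(pool)
  mol <- update_activation_mol(mol, params)
  compact_molecules(mol, pool)
}

update_activation_mol <- function(mol, params) {
  if (!nrow(mol)) return(mol)
  act <- mol$p5 == "activated_2AI"
  pho <- mol$p5 == "phosphate"
  u <- stats::runif(nrow(mol))
  mol$p5[act & u < params$k_hyd] <- "phosphate"
  mol$p5[pho & u < params$k_act] <- "activated_2AI"
  mol
}

#' Spontaneous strand cleavage and 3'-end fate chemistry
#'
#' Applied during the denatured phase of a cycle. Pre-existing 2',3'-cyclic
#' phosphate termini hydrolyse with probability `h_cp` to a 2'- or
#' 3'-phosphate (equal odds; only the 3'-phosphate can grow again, at the
#' cost of a pyrophosphate linkage). Then every internal phosphodiester
#' bond breaks with probability `p_cleave` — the upstream product gains a
#' 2',3'-cyclic phosphate, the downstream product a 5'-hydroxyl (and so can
#' never ligate onto an upstream oligo) — while internal pyrophosphate
#' linkages break with probability `p_pp`, the upstream product again
#' ending in a cyclic phosphate but the downstream product keeping a normal
#' 5'-phosphate.
#'
#' @inheritParams update_activation
#' @return the updated pool.
#' @export
cleave_strands <- function(pool, params = reaction_params(), seed = NULL) {
  if (inherits(params, "vcg_sim_params")) params <- params$reaction
  if (!is.null(seed)) set.seed(seed)
  mol <- expand_pool(pool)
  mol <- cleave_mol(mol, params)
  compact_molecules(mol, pool)
}

cleave_mol <- function(mol, params) {
  if (!nrow(mol)) return(mol)
  # cyclic-phosphate hydrolysis on existing termini
  cp <- which(mol$p3 == "cyclic_phosphate")
  if (length(cp)) {
    h <- cp[stats::runif(length(cp)) < params$h_cp]
    if (length(h))
      mol$p3[h] <- ifelse(stats::runif(length(h)) < 0.5,
                          "phosphate_2p", "phosphate_3p")
  }
  if (params$p_cleave <= 0 && params$p_pp <= 0) return(mol)
  k <- nchar(mol$seq)
  has_pp <- mol$pp != ""
  # screen: probability a molecule breaks anywhere this cycle
  n_pp <- ifelse(has_pp, lengths(regmatches(mol$pp,
                                            gregexpr(",", mol$pp))) + 1L, 0L)
  p_any <- 1 - (1 - params$p_cleave)^pmax(0L, k - 1L - n_pp) *
    (1 - params$p_pp)^n_pp
  hit <- which(stats::runif(nrow(mol)) < p_any)
  if (!length(hit)) return(mol)
  out <- vector("list", length(hit))
  for (w in seq_along(hit)) {
    i <- hit[w]
    ppb <- parse_pp(mol$pp[i])
    prob <- rep(params$p_cleave, k[i] - 1L)
    prob[ppb] <- params$p_pp
    breaks <- which(stats::runif(k[i] - 1L) < prob)
    while (!length(breaks)) breaks <- which(stats::runif(k[i] - 1L) < prob)
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, k[i])
    frs <- lapply(seq_along(starts), function(f) {
      s <- starts[f]; e <- ends[f]
      p5 <- if (s == 1L) mol$p5[i]
            else if ((s - 1L) %in% ppb) "phosphate" else "hydroxyl"
      p3 <- if (e == k[i]) mol$p3[i] else "cyclic_phosphate"
      keep_pp <- ppb[ppb >= s & ppb < e] - (s - 1L)
      data.frame(seq = substr(mol$seq[i], s, e), p5 = p5, p3 = p3,
                 stalled = if (e == k[i]) mol$stalled[i] else FALSE,
                 pp = format_pp(keep_pp), stringsAsFactors = FALSE)
    })
    out[[w]] <- do.call(rbind, frs)
  }
  res <- rbind(mol[-hit, , drop = FALSE], do.call(rbind, out))
  rownames(res) <- NULL
  res
}

# --- the full environmental cycle -------------------------------------------

#' Advance a protocell by one denature/anneal environmental cycle
#'
#' One cycle is: (1) denature — every non-inert duplex separates; (2)
#' strand cleavage and 3'-end fate chemistry ([cleave_strands()]); (3)
#' chemostat feed of activated monomers and bridged dinucleotides to their
#' set-points; (4) re-annealing into a fresh kinetically trapped
#' configuration ([anneal()]); (5) toehold invasion opening
#' ([invasion_open()]); (6) site classification ([classify_sites()]); (7)
#' Bernoulli firing of extension / ligation / initiation sites in random
#' order; (8) 5'-activation turnover ([update_activation()]); (9)
#' cyclization loss of unbound short oligos; (10) duplexes with match
#' length >= `dead_end_len` become inert dead ends. The nucleotide mass
#' ledger is checked across the cycle: feed is the only source, cyclization
#' the only sink, and an imbalance aborts with an internal error.
#'
#' @param state a [protocell_state()].
#' @param params a [sim_params()].
#' @param seed optional integer seed.
#' @return the updated `vcg_protocell` (cycle incremented; `$last` holds
#'   the cycle's binding/site/event summary).
#' @export
step_cycle <- function(state, params = sim_params(), seed = NULL) {
  stopifnot(inherits(state, "vcg_protocell"),
            inherits(params, "vcg_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  rp <- params$reaction
  pool <- state$pool
  before <- oligo_units(pool) + fed_units(pool)
  fed0 <- pool$ledger$fed_units
  lost0 <- pool$ledger$lost_units

  # (1)-(2): denatured phase — cleavage fates on free single strands
  mol <- cleave_mol(expand_pool(pool), rp)
  pool <- compact_molecules(mol, pool)
  # (3): feed
  pool <- feed_pool(pool, rp)
  # (4)-(5): anneal, invasion
  config <- anneal(pool, params)
  config <- invasion_open(config, pool, params)
  # (6)-(7): classify and fire
  sites <- classify_sites(config, pool, rp)
  ctx <- fire_sites(config, pool, sites, rp)
  # (8): activation turnover
  ctx$mol <- update_activation_mol(ctx$mol, rp)
  # (9): cyclization loss of short unbound oligos
  bound <- seq_len(nrow(ctx$mol)) %in%
    c(ctx$bindings$templ[ctx$bind_alive], ctx$bindings$oligo[ctx$bind_alive])
  short <- ctx$alive & !bound & nchar(ctx$mol$seq) <= rp$cyc_len
  cyc <- which(short)[stats::runif(sum(short)) < rp$p_cyc]
  if (length(cyc)) {
    ctx$ledger$lost_units <- ctx$ledger$lost_units +
      sum(nchar(ctx$mol$seq[cyc]))
    ctx$alive[cyc] <- FALSE
  }
  # (10): dead-end duplexes become inert
  dead <- which(ctx$bind_alive & ctx$bindings$len >= rp$dead_end_len)
  inert_new <- list()
  for (bi in dead) {
    t <- ctx$bindings$templ[bi]; o <- ctx$bindings$oligo[bi]
    if (!ctx$alive[t] || !ctx$alive[o]) next
    inert_new[[length(inert_new) + 1L]] <-
      data.frame(seq_a = ctx$mol$seq[t], seq_b = ctx$mol$seq[o],
                 count = 1, stringsAsFactors = FALSE)
    ctx$alive[c(t, o)] <- FALSE
  }
  if (length(inert_new))
    state$inert <- aggregate_inert(rbind(state$inert,
                                         do.call(rbind, inert_new)))

  new_pool <- ctx_to_pool(ctx, pool)
  inert_delta <- if (length(inert_new))
    sum(vapply(inert_new, function(x) nchar(x$seq_a) + nchar(x$seq_b),
               0)) else 0
  after <- oligo_units(new_pool) + fed_units(new_pool) + inert_delta
  fed_in <- new_pool$ledger$fed_units - fed0
  lost <- new_pool$ledger$lost_units - lost0
  if (abs((after + lost) - (before + fed_in)) > 1e-6)
    stop("internal error: nucleotide mass ledger imbalance (",
         after + lost - before - fed_in, " nt)")

  state$pool <- new_pool
  state$cycle <- state$cycle + 1L
  state$last <- list(n_bindings = sum(ctx$bind_alive),
                     sites = table(sites$kind), events = ctx$events)
  state
}

fed_units <- function(pool) {
  sum(pool$fed$monomers) + 2 * sum(pool$fed$bridged)
}

aggregate_inert <- function(inert) {
  if (!nrow(inert)) return(inert)
  key <- paste(inert$seq_a, inert$seq_b, sep = "\r")
  agg <- rowsum(inert$count, key)
  first <- inert[match(rownames(agg), key), , drop = FALSE]
  first$count <- as.numeric(agg[, 1])
  rownames(first) <- NULL
  first
}

#' Nucleotide mass ledger of a protocell state
#'
#' Nucleotide units by compartment. Across any reaction step the grand
#' total minus cumulative feed plus cumulative cyclization loss is
#' invariant; [step_cycle()] enforces this every cycle.
#'
#' @param state a [protocell_state()].
#' @return named numeric: `oligos`, `monomers`, `bridged`, `inert`,
#'   `lost_cyclized`, `fed_in`, `total`.
#' @export
mass_ledger <- function(state) {
  pool <- state$pool
  inert_units <- if (nrow(state$inert))
    sum((nchar(state$inert$seq_a) + nchar(state$inert$seq_b)) *
          state$inert$count) else 0
  c(oligos = oligo_units(pool),
    monomers = sum(pool$fed$monomers),
    bridged = 2 * sum(pool$fed$bridged),
    inert = inert_units,
    lost_cyclized = pool$ledger$lost_units,
    fed_in = pool$ledger$fed_units,
    total = oligo_units(pool) + fed_units(pool) + inert_units)
}
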