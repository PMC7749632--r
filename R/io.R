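#' Generate a seeded random circular genome fixture
#'
#' @param length circle length `L` (>= 4); the default 16 matches the
#'   worked concentration ledger for a 16-nt virtual circular genome.
#' @param alphabet `"ACGU"` or `"ACIU"`.
#' @param purine_bias per-position probability that the plus strand
#'   carries a purine (A, G or I).
#' @param seed integer seed; the same arguments and seed always give the
#'   same genome.
#' @param name genome name.
#' @return a [vcg_genome()].
#' @export
generate_fixture_genome <- function(length = 16,
                                    alphabet = c("ACGU", "ACIU"),
                                    purine_bias = 0.5, seed = NULL,
                                    name = "vcg") {
  alphabet <- match.arg(alphabet)
  stopifnot(length >= 4, purine_bias >= 0, purine_bias <= 1)
  if (!is.null(seed)) set.seed(substream_seed(seed, "fixture"))
  pur <- if (alphabet == "ACGU") c("A", "G") else c("A", "I")
  pyr <- c("C", "U")
  is_pur <- stats::runif(length) < purine_bias
  chars <- ifelse(is_pur, sample(pur, length, replace = TRUE),
                  sample(pyr, length, replace = TRUE))
  vcg_genome(paste(chars, collapse = ""), alphabet = alphabet,
             name = name)
}

#' Read and write virtual circular genomes as FASTA
#'
#' A genome is stored as a single FASTA record whose header carries
#' `circular=true length=L alphabet=ACGU|ACIU`.
#'
#' @param genome a [vcg_genome()].
#' @param path file path.
#' @return `write_genome_fasta` returns `path` invisibly;
#'   `read_genome_fasta` returns a [vcg_genome()].
#' @examples
#' g <- read_genome_fasta(system.file("extdata", "vcg16.fasta",
#'                                    package = "vcgsim"))
#' g$L
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "vcg_genome"))
  set <- Biostrings::BStringSet(genome$seq)
  names(set) <- sprintf("%s circular=true length=%d alphabet=%s",
                        genome$name, genome$L, genome$alphabet)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1)
    stop("genome FASTA must contain exactly one circular record: ", path)
  header <- names(set)[1]
  fields <- parse_header_fields(header)
  alphabet <- fields[["alphabet"]] %||% "ACGU"
  name <- strsplit(header, " ")[[1]][1]
  g <- vcg_genome(as.character(set[[1]]), alphabet = alphabet,
                  name = name)
  if (!is.null(fields[["length"]]) &&
      as.integer(fields[["length"]]) != g$L)
    stop("header length=", fields[["length"]],
         " disagrees with sequence length ", g$L, " in ", path)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_header_fields <- function(header) {
  toks <- strsplit(header, "[ \t]+")[[1]]
  kv <- toks[grepl("=", toks, fixed = TRUE)]
  parts <- strsplit(kv, "=", fixed = TRUE)
  stats::setNames(lapply(parts, `[`, 2), vapply(parts, `[`, "", 1))
}

#' Read and write oligonucleotide pools
#'
#' The pool file is FASTA with per-record header fields
#' `count=<int> p5=<state> p3=<state>` (and optionally `pp=<bonds>`
#' `stalled=true`); fed species live in a sidecar TSV with columns
#' `species` (e.g. `monomer_A`, `bridged_GC`) and `count`. A write/read
#' round trip reproduces species counts and end states exactly.
#'
#' @param pool a [vcg_pool()].
#' @param path FASTA path; the fed sidecar is `<path>.fed.tsv`.
#' @param volume,alphabet pool geometry for `read_pool_fasta` (volume in
#'   liters).
#' @return `write_pool_fasta` returns `path` invisibly; `read_pool_fasta`
#'   a [vcg_pool()].
#' @export
write_pool_fasta <- function(pool, path) {
  stopifnot(inherits(pool, "vcg_pool"))
  sp <- pool$species
  headers <- sprintf("sp%d count=%d p5=%s p3=%s%s%s",
                     seq_len(nrow(sp)), as.integer(sp$count), sp$p5,
                     sp$p3,
                     ifelse(sp$pp != "", paste0(" pp=", sp$pp), ""),
                     ifelse(sp$stalled, " stalled=true", ""))
  set <- Biostrings::BStringSet(sp$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  fed <- rbind(
    data.frame(species = paste0("monomer_", names(pool$fed$monomers)),
               count = unname(pool$fed$monomers)),
    data.frame(species = paste0("bridged_", names(pool$fed$bridged)),
               count = unname(pool$fed$bridged)))
  utils::write.table(fed, paste0(path, ".fed.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_fasta
#' @export
read_pool_fasta <- function(path, volume = 1e-15, alphabet = "ACGU") {
  set <- Biostrings::readBStringSet(path)
  sp <- species_frame()
  if (length(set)) {
    fields <- lapply(names(set), parse_header_fields)
    getf <- function(nm, default)
      vapply(fields, function(f) f[[nm]] %||% default, "")
    sp <- species_frame(
      seq = as.character(set),
      p5 = getf("p5", "phosphate"),
      p3 = getf("p3", "diol"),
      stalled = getf("stalled", "false") == "true",
      pp = getf("pp", ""),
      count = as.numeric(getf("count", "1")))
  }
  fed <- empty_fed(alphabet)
  fed_path <- paste0(path, ".fed.tsv")
  if (file.exists(fed_path)) {
    tab <- utils::read.delim(fed_path, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(tab))) {
      kind <- sub("_.*$", "", tab$species[i])
      key <- sub("^[a-z]+_", "", tab$species[i])
      slot <- c(monomer = "monomers", bridged = "bridged")[[kind]]
      fed[[slot]][key] <- tab$count[i]
    }
  }
  vcg_pool(aggregate_species(sp), fed = fed, volume = volume,
           alphabet = alphabet)
}

#' Default run configuration
#'
#' The structured configuration consumed by the `vcg` command line
#' interface and [read_run_config()]/[write_run_config()] (YAML on disk).
#' Pre-filled with the reference study conditions: a 16-nt genome,
#' fragment lengths 2-12, gradient ratio 2 anchored at 1 mM dinucleotides
#' (0.5 mM trimers follow), 5 mM activated monomers and 1 mM bridged
#' dinucleotides as the chemostat feed, and a 50 nm simulation vesicle.
#' Every stochastic run is fully determined by (config, master seed).
#'
#' @param seed master seed recorded in the config.
#' @return nested list of class `vcg_run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    genome = list(fasta = NULL, length = 16, alphabet = "ACGU",
                  purine_bias = 0.5),
    fragments = list(min_len = 2, max_len = 12),
    gradient = list(ratio = 2, anchor_length = 2,
                    anchor_concentration = 1e-3),
    energy = list(dG_bp = -2.5, temperature = 298.15,
                  pair_modifiers = list(AU = 1, GC = 1, IC = 0.6),
                  dG_assoc = NULL),
    reaction = as.list(unclass(reaction_params())),
    protocell = list(diameter = 5e-8, n_generations = 5,
                     division_trigger = "mass_doubling", k_cycles = 10,
                     max_cycles_per_generation = 60, max_cycles = 500),
    output_dir = "vcg_out",
    seed = seed), class = "vcg_run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param config a `vcg_run_config` (any nested list with the same shape).
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the configuration list. Round trips are lossless.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_run_config())
  for (nm in names(base)) {
    if (is.list(base[[nm]]) && !is.null(cfg[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], cfg[[nm]])
    else if (!is.null(cfg[[nm]])) base[[nm]] <- cfg[[nm]]
  }
  structure(base, class = "vcg_run_config")
}

#' Materialise the R objects a run configuration describes
#'
#' Builds the genome (from FASTA or the seeded generator), parameter
#' bundle and gradient spec encoded in a `vcg_run_config`; used by the
#' `vcg` command line interface.
#'
#' @param cfg a configuration from [read_run_config()] or
#'   [default_run_config()].
#' @return list with `genome`, `params` (a [sim_params()]), `gradient`,
#'   and the input `cfg`.
#' @export
config_objects <- function(cfg) {
  genome <- if (!is.null(cfg$genome$fasta))
    read_genome_fasta(cfg$genome$fasta)
  else generate_fixture_genome(cfg$genome$length, cfg$genome$alphabet,
                               cfg$genome$purine_bias, seed = cfg$seed)
  energy <- energy_params(
    dG_bp = cfg$energy$dG_bp, temperature = cfg$energy$temperature,
    pair_modifiers = unlist(cfg$energy$pair_modifiers),
    dG_assoc = cfg$energy$dG_assoc)
  reaction <- do.call(reaction_params, cfg$reaction)
  gradient <- gradient_spec(cfg$gradient$ratio, cfg$gradient$anchor_length,
                            cfg$gradient$anchor_concentration)
  list(genome = genome, params = sim_params(energy, reaction),
       gradient = gradient, cfg = cfg)
}
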