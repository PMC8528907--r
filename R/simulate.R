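#' Simulation configuration for specialist/generalist communities
#'
#' The generator emulates the community structure the
#' specialization-disturbance hypothesis predicts: many specialists with
#' small functional repertoires drawn mostly from a shared core pool of
#' functions, and a few generalists with large repertoires drawn mostly from
#' a broad accessory pool. Disturbance acts as selection on repertoire size
#' (niche breadth), so a disturbed community concentrates abundance on the
#' generalists: fewer effective taxa, but a broader set of expressed
#' functions. Reads are multinomial draws, giving paired OTU and GO-term
#' count tables.
#'
#' The defaults define the reference scenario: control communities that are
#' taxon-rich but function-concentrated, disturbed communities that are
#' taxon-poor but function-rich. They are simulator conventions chosen to
#' mirror the direction of the effects seen in oiled-vs-control beach-sand
#' communities, not estimates of any real system's parameters.
#'
#' @param n_specialists,n_generalists Number of taxa per guild.
#' @param specialist_repertoire_range,generalist_repertoire_range Inclusive
#'   `(low, high)` bounds for per-taxon repertoire sizes (numbers of distinct
#'   GO molecular-function terms); sizes are drawn uniformly.
#' @param core_pool_size,accessory_pool_size Sizes of the shared core and
#'   broad accessory function pools.
#' @param specialist_core_fraction,generalist_core_fraction Share of a
#'   taxon's repertoire drawn (without replacement) from the core pool.
#' @param abundance_lognormal_sigma SD (log scale) of the i.i.d. lognormal
#'   baseline abundances.
#' @param selection_strength Disturbance selection strength `s >= 0` applied
#'   to disturbed samples (see [apply_disturbance()]).
#' @param read_depth_taxonomic,read_depth_functional Reads per sample for the
#'   OTU and GO-term assays.
#' @param n_replicates_per_group Independent communities per group.
#' @param seed Root RNG seed; per-sample child seeds are derived from it and
#'   recorded in the output metadata.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_specialists = 150,
                              n_generalists = 10,
                              specialist_repertoire_range = c(40, 120),
                              generalist_repertoire_range = c(400, 800),
                              core_pool_size = 150,
                              accessory_pool_size = 5000,
                              specialist_core_fraction = 0.8,
                              generalist_core_fraction = 0.1,
                              abundance_lognormal_sigma = 1.0,
                              selection_strength = 2.5,
                              read_depth_taxonomic = 1e5,
                              read_depth_functional = 1e5,
                              n_replicates_per_group = 5,
                              seed = 42) {
  cfg <- list(
    n_specialists = as.integer(n_specialists),
    n_generalists = as.integer(n_generalists),
    specialist_repertoire_range = as.integer(specialist_repertoire_range),
    generalist_repertoire_range = as.integer(generalist_repertoire_range),
    core_pool_size = as.integer(core_pool_size),
    accessory_pool_size = as.integer(accessory_pool_size),
    specialist_core_fraction = specialist_core_fraction,
    generalist_core_fraction = generalist_core_fraction,
    abundance_lognormal_sigma = abundance_lognormal_sigma,
    selection_strength = selection_strength,
    read_depth_taxonomic = as.integer(read_depth_taxonomic),
    read_depth_functional = as.integer(read_depth_functional),
    n_replicates_per_group = as.integer(n_replicates_per_group),
    seed = as.integer(seed)
  )
  pool <- cfg$core_pool_size + cfg$accessory_pool_size
  for (g in c("specialist", "generalist")) {
    r <- cfg[[paste0(g, "_repertoire_range")]]
    if (length(r) != 2 || r[1] < 1 || r[1] > r[2])
      stop(g, " repertoire range must be (low, high) with 1 <= low <= high")
    if (r[2] > pool)
      stop(g, " repertoire range exceeds the total function pool (", pool, ")")
    f <- cfg[[paste0(g, "_core_fraction")]]
    if (f < 0 || f > 1) stop(g, " core fraction must be in [0, 1]")
  }
  if (cfg$n_specialists < 0 || cfg$n_generalists < 0 ||
      cfg$n_specialists + cfg$n_generalists < 1)
    stop("need at least one taxon")
  if (cfg$selection_strength < 0) stop("selection strength must be >= 0")
  if (cfg$read_depth_taxonomic < 1 || cfg$read_depth_functional < 1)
    stop("read depths must be >= 1")
  if (cfg$n_replicates_per_group < 1) stop("need >= 1 replicate per group")
  if (cfg$abundance_lognormal_sigma < 0) stop("lognormal sigma must be >= 0")
  structure(cfg, class = "simulation_config")
}

#' Generate one community of taxon profiles
#'
#' Per taxon: a repertoire size drawn uniformly from its guild's range, the
#' repertoire itself drawn without replacement — `round(core_fraction * size)`
#' functions from the core pool (clamped to what each pool can supply) and
#' the rest from the accessory pool — and a baseline abundance drawn i.i.d.
#' lognormal(0, sigma), then normalized to sum to 1.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the same seed reproduces the same community.
#' @return A `community_state`: list with `profiles` (per-taxon list of
#'   `taxon_id`, `guild`, `repertoire`, `repertoire_size`), `abundances`
#'   (named, summing to 1) and `disturbed = FALSE`.
#' @export
generate_community <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  core_ids <- sprintf("GO:C%06d", seq_len(config$core_pool_size))
  acc_ids <- sprintf("GO:A%06d", seq_len(config$accessory_pool_size))
  guilds <- c(rep("specialist", config$n_specialists),
              rep("generalist", config$n_generalists))
  profiles <- lapply(seq_along(guilds), function(i) {
    guild <- guilds[i]
    r <- config[[paste0(guild, "_repertoire_range")]]
    size <- if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)
    frac <- config[[paste0(guild, "_core_fraction")]]
    n_core <- round(frac * size)
    # clamp so both pools can supply their share
    n_core <- min(n_core, config$core_pool_size)
    n_core <- max(n_core, size - config$accessory_pool_size)
    repertoire <- c(sample(core_ids, n_core),
                    sample(acc_ids, size - n_core))
    list(taxon_id = sprintf("OTU%04d", i), guild = guild,
         repertoire = repertoire, repertoire_size = size)
  })
  a <- rlnorm(length(guilds), 0, config$abundance_lognormal_sigma)
  a <- a / sum(a)
  names(a) <- vapply(profiles, `[[`, character(1), "taxon_id")
  structure(list(profiles = profiles, abundances = a, disturbed = FALSE),
            class = "community_state")
}

#' Apply disturbance as selection on repertoire size
#'
#' Reweights abundances by niche breadth:
#' \deqn{w_i \propto a_i \exp\!\left(s \, \frac{|R_i| - \overline{|R|}}
#'   {\mathrm{sd}(|R|)}\right),}
#' renormalized to sum to 1, where \eqn{|R_i|} is taxon i's repertoire size
#' (sample SD, n - 1 denominator). `s = 0` is the identity; for `s > 0` the
#' total generalist share strictly increases, emulating disturbances that
#' select against specialists and favor generalists.
#'
#' @param state A `community_state`.
#' @param s Selection strength, `s >= 0`.
#' @return The reweighted `community_state` with `disturbed = s > 0`.
#' @export
apply_disturbance <- function(state, s) {
  stopifnot(inherits(state, "community_state"))
  if (s < 0) stop("selection strength must be >= 0")
  sizes <- vapply(state$profiles, `[[`, numeric(1), "repertoire_size")
  sd_r <- sd(sizes)
  if (length(sizes) < 2 || sd_r == 0)
    stop("repertoire sizes have zero spread; selection on niche breadth is undefined")
  w <- state$abundances * exp(s * (sizes - mean(sizes)) / sd_r)
  state$abundances <- w / sum(w)
  state$disturbed <- s > 0
  state
}

#' Total abundance share held by generalists
#' @param state A `community_state`.
#' @return Fraction in \[0, 1\].
#' @export
generalist_share <- function(state) {
  stopifnot(inherits(state, "community_state"))
  gen <- vapply(state$profiles, `[[`, character(1), "guild") == "generalist"
  sum(state$abundances[gen])
}

#' Sample taxonomic (OTU) reads from a community
#'
#' One multinomial draw of `depth` reads over taxon abundances, emulating
#' 16S fragment counting.
#'
#' @param state A `community_state`.
#' @param depth Number of reads (`>= 1`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param sample_id Sample ID attached to the result.
#' @return An [abundance_vector()] of OTU counts.
#' @export
sample_taxonomic_reads <- function(state, depth, seed = NULL,
                                   sample_id = NA_character_) {
  stopifnot(inherits(state, "community_state"))
  if (depth < 1) stop("read depth must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  counts <- drop(rmultinom(1, depth, state$abundances))
  names(counts) <- names(state$abundances)
  abundance_vector(counts, sample_id = sample_id)
}

#' Marginal function (GO-term) sampling probabilities of a community
#'
#' Each read picks a taxon proportional to abundance, then one function
#' uniformly from that taxon's repertoire, so the marginal probability of
#' function g is \eqn{\sum_i a_i [g \in R_i] / |R_i|}.
#'
#' @param state A `community_state`.
#' @return Named probability vector over all functions present, summing to 1.
#' @export
function_marginals <- function(state) {
  stopifnot(inherits(state, "community_state"))
  contrib <- lapply(seq_along(state$profiles), function(i) {
    p <- state$profiles[[i]]
    if (length(p$repertoire) == 0)
      stop("taxon ", p$taxon_id, " has an empty repertoire")
    rep(state$abundances[i] / length(p$repertoire), length(p$repertoire))
  })
  ids <- unlist(lapply(state$profiles, `[[`, "repertoire"), use.names = FALSE)
  m <- rowsum(unlist(contrib), group = ids)
  p <- drop(m)
  names(p) <- rownames(m)
  p / sum(p)
}

#' Sample functional (GO-term) reads from a community
#'
#' One multinomial draw of `depth` reads over the closed-form function
#' marginals of [function_marginals()] (equivalent to per-read hierarchical
#' taxon-then-function sampling).
#'
#' @inheritParams sample_taxonomic_reads
#' @return An [abundance_vector()] of GO-term counts.
#' @export
sample_functional_reads <- function(state, depth, seed = NULL,
                                    sample_id = NA_character_) {
  stopifnot(inherits(state, "community_state"))
  if (depth < 1) stop("read depth must be >= 1")
  p <- function_marginals(state)
  if (!is.null(seed)) set.seed(seed)
  counts <- drop(rmultinom(1, depth, p))
  names(counts) <- names(p)
  abundance_vector(counts, sample_id = sample_id)
}

#' Generate a full synthetic disturbance experiment
#'
#' Builds `n_replicates_per_group` control and disturbed samples. Each
#' replicate is an independent community (replicates model separate
#' chambers, not resamples of one community): community i uses child seed
#' `seed + i`, its taxonomic and functional reads child seeds
#' `seed + 1000 + i` and `seed + 2000 + i` (all recorded in the metadata).
#' Control samples are sampled at `s = 0`, disturbed samples after
#' [apply_disturbance()] at `s = selection_strength`.
#'
#' @param config A [simulation_config()].
#' @return A list with `taxonomic` and `functional` `count_table`s sharing
#'   sample IDs, and `metadata` (`sample_metadata`, one row per sample per
#'   assay, with the child seeds in columns `community_seed`, `read_seed`).
#' @export
generate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n_rep <- config$n_replicates_per_group
  groups <- rep(c("control", "disturbed"), each = n_rep)
  ids <- sprintf("%s_%d", groups, rep(seq_len(n_rep), 2))
  tax <- list(); fun <- list(); md <- list()
  for (i in seq_along(ids)) {
    cseed <- config$seed + i
    comm <- generate_community(config, seed = cseed)
    if (groups[i] == "disturbed")
      comm <- apply_disturbance(comm, config$selection_strength)
    tseed <- config$seed + 1000L + i
    fseed <- config$seed + 2000L + i
    tax[[i]] <- sample_taxonomic_reads(comm, config$read_depth_taxonomic,
                                       seed = tseed, sample_id = ids[i])
    fun[[i]] <- sample_functional_reads(comm, config$read_depth_functional,
                                        seed = fseed, sample_id = ids[i])
    md[[i]] <- data.frame(
      sample_id = ids[i], group = groups[i],
      assay = c("taxonomic", "functional"),
      label = sprintf("replicate_%d", rep(seq_len(n_rep), 2)[i]),
      community_seed = cseed, read_seed = c(tseed, fseed),
      stringsAsFactors = FALSE
    )
  }
  list(
    taxonomic = vectors_to_table(tax),
    functional = vectors_to_table(fun),
    metadata = as_sample_metadata(do.call(rbind, md))
  )
}

#' Assemble abundance vectors into a count table
#'
#' Features are the union over samples; absent features get 0.
#'
#' @param vectors List of named [abundance_vector()]s with distinct sample IDs.
#' @return A `count_table`.
#' @export
vectors_to_table <- function(vectors) {
  ids <- vapply(vectors, function(v) v$sample_id, character(1))
  feats <- sort(unique(unlist(lapply(vectors, function(v) names(v$counts)))))
  if (is.null(feats) || any(feats == ""))
    stop("all abundance vectors must have named counts")
  mat <- matrix(0, nrow = length(feats), ncol = length(vectors),
                dimnames = list(feats, ids))
  for (j in seq_along(vectors)) mat[names(vectors[[j]]$counts), j] <- vectors[[j]]$counts
  as_count_table(mat)
}

#' Write a simulated experiment to an output directory
#'
#' Emits `taxonomic_counts.tsv`, `functional_counts.tsv`, `metadata.tsv` and
#' a YAML echo of the generating configuration (`config.yml`).
#'
#' @param experiment Result of [generate_experiment()].
#' @param config The [simulation_config()] used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(experiment, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(experiment$taxonomic, file.path(dir, "taxonomic_counts.tsv"))
  write_count_table(experiment$functional, file.path(dir, "functional_counts.tsv"))
  write_sample_metadata(experiment$metadata, file.path(dir, "metadata.tsv"))
  yaml::write_yaml(unclass(config), file.path(dir, "config.yml"))
  invisible(dir)
}
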