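# shared fixtures built in code

# a small features-x-samples table with known column sums (5, 3)
tiny_table <- function() {
  as_count_table(matrix(c(4, 1, 0, 3), nrow = 2,
                        dimnames = list(c("f1", "f2"), c("s1", "s2"))))
}

tiny_metadata <- function() {
  as_sample_metadata(data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    group = c("disturbed", "disturbed", "control", "control"),
    assay = "taxonomic",
    label = ""
  ))
}

# random abundance vector: S features, exponential abundance profile,
# multinomial counts, zero features dropped by the constructor
random_vector <- function(S = 8, n = 100, id = "r") {
  x <- drop(rmultinom(1, n, rexp(S)))
  x <- x[x > 0]
  if (length(x) == 0 || sum(x) < 2) x <- c(x, 2)
  abundance_vector(x, sample_id = id)
}

# a tiny two-guild community built by hand (bypasses the generator) for
# closed-form disturbance checks
two_taxon_state <- function(sizes = c(100, 500), a = c(0.5, 0.5)) {
  profiles <- list(
    list(taxon_id = "OTU0001", guild = "specialist",
         repertoire = sprintf("GO:S%03d", seq_len(sizes[1])),
         repertoire_size = sizes[1]),
    list(taxon_id = "OTU0002", guild = "generalist",
         repertoire = sprintf("GO:G%03d", seq_len(sizes[2])),
         repertoire_size = sizes[2])
  )
  names(a) <- c("OTU0001", "OTU0002")
  structure(list(profiles = profiles, abundances = a, disturbed = FALSE),
            class = "community_state")
}

# a small, fast simulation scenario for pipeline tests
small_config <- function(seed = 7, s = 2.5) {
  simulation_config(
    n_specialists = 40, n_generalists = 5,
    specialist_repertoire_range = c(10, 30),
    generalist_repertoire_range = c(100, 200),
    core_pool_size = 60, accessory_pool_size = 1000,
    read_depth_taxonomic = 5000, read_depth_functional = 5000,
    n_replicates_per_group = 3, selection_strength = s, seed = seed
  )
}
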