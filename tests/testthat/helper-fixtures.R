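# small shared fixtures, built in code

# fast simulation config for tests that do not need the full design
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, ...)
}

# genotype ranks printed for the 12 genotypes across the five
# drought-performance traits (grain number, biomass at 22 DAD, grain
# weight, tiller number gain, spike number), with the published Total
ranking_fixture <- function() {
  tibble::tribble(
    ~genotype,   ~GrainNumber, ~Biomass, ~GrainWeight, ~TillerNumberGain, ~SpikeNumber, ~Total,
    "PPPW_017",  4,  2,  1,  3,  2,  1,
    "PPPW_025",  6,  1,  7,  1,  3,  2,
    "PPPW_033",  1,  5,  2,  4,  4,  3,
    "PPPW_023",  7,  3,  5,  2,  1,  4,
    "PPPW_012",  5,  7,  4,  6,  5,  5,
    "PPPW_046",  2,  4,  6, 12, 10,  6,
    "PPPW_016",  8,  6,  3,  8,  7,  7,
    "PPPW_034",  3, 10,  8,  7,  9,  8,
    "PPPW_011", 10,  8, 10,  5,  6,  9,
    "PPPW_007",  9,  9,  9,  9,  8, 10,
    "PPPW_004", 11, 11, 11, 10, 11, 11,
    "PPPW_003", 12, 12, 12, 11, 12, 12
  )
}

# long (genotype, trait, rank) form of the fixture
ranking_fixture_long <- function() {
  tidyr::pivot_longer(
    dplyr::select(ranking_fixture(), -"Total"),
    -genotype, names_to = "trait", values_to = "rank"
  )
}

# minimal long intensity table: values is a named list feature -> numeric
# vector over samples; blanks optional named list feature -> vector
make_intensity <- function(values, blanks = NULL, treatment = NULL,
                           timepoint = 22) {
  n <- length(values[[1]])
  samples <- sprintf("s%02d", seq_len(n))
  trt <- treatment %||% rep(c("control", "drought"), length.out = n)
  long <- tidyr::expand_grid(sample_id = samples,
                             feature_id = names(values))
  long$intensity <- unname(unlist(lapply(seq_len(n), function(i) {
    vapply(names(values), function(f) values[[f]][i], numeric(1))
  })))
  long$treatment <- rep(trt, each = length(values))
  long$genotype <- "G01"
  long$replicate <- rep(seq_len(n), each = length(values))
  long$timepoint <- timepoint
  long$is_blank <- FALSE
  if (!is.null(blanks)) {
    nb <- length(blanks[[1]])
    bl <- tidyr::expand_grid(sample_id = sprintf("b%02d", seq_len(nb)),
                             feature_id = names(blanks))
    bl$intensity <- unname(unlist(lapply(seq_len(nb), function(i) {
      vapply(names(blanks), function(f) blanks[[f]][i], numeric(1))
    })))
    bl$treatment <- NA_character_
    bl$genotype <- NA_character_
    bl$replicate <- rep(seq_len(nb), each = length(blanks))
    bl$timepoint <- timepoint
    bl$is_blank <- TRUE
    long <- dplyr::bind_rows(long, bl)
  }
  long
}

`%||%` <- rlang::`%||%`
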