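# Shared fixtures, built lazily and cached for the duration of the test run.
# Everything is generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

fix_lib <- function() fixture("lib", function() make_library(1L))

fix_blueprints <- function() fixture("bps", function() {
  builtin_blueprints(fix_lib())
})

fix_allele <- function(name) {
  fixture(paste0("allele_", name), function() {
    build_allele(fix_lib(), fix_blueprints()[[name]])
  })
}

# the default study-condition simulation (three-allele genotype, 50X long
# reads, 100X short reads) and its full resolution
fix_sim <- function() fixture("sim", function() {
  run_simulate(default_config(seed = 1L))
})

fix_bundle <- function() fixture("bundle", function() {
  run_resolve(fix_sim(), default_config(seed = 1L))
})

# small error-free full-span long-read simulation used by oracle tests
# (equal abundances so every allele gets several whole-allele reads)
fix_fullspan <- function() fixture("fullspan", function() {
  model <- long_read_model(mean_len = 1e6, min_len = 100, max_len = 2e6,
                           sub = 0, ins = 0, del = 0)
  gt <- data.frame(name = c("alleleA", "alleleB", "alleleC"),
                   abundance = c(1, 1, 1))
  simulate_long(fix_lib(), gt, model, coverage_per_allele = 3, seed = 11L,
                blueprints = fix_blueprints())
})

random_reads <- function(n, len, seed = 3L) {
  withr::with_seed(seed, {
    read_set(sprintf("r%03d", seq_len(n)),
             vapply(seq_len(n), function(i)
               paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""), ""))
  })
}
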