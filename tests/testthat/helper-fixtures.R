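# Shared simulated fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# the full duplication study plan: 550 genes over 9 chromosomes
fx_plan_ann <- function() fixture("plan_ann", function() {
  simulate_annotation(sim_config(seed = 101))
})

# small two-chromosome annotation for I/O and profile tests
fx_small_ann <- function() fixture("small_ann", function() {
  cfg <- sim_config(seed = 102,
                    chrom_lengths = c(Chr1 = 200000L, Chr2 = 200000L),
                    plan = dup_plan(singleton = 40, tandem_pairs = 5,
                                    proximal_pairs = 5, dispersed_pairs = 5,
                                    seg2 = 1, seg3 = 0, genes_per_segment = 6),
                    te_count = 30L)
  list(cfg = cfg, ann = simulate_annotation(cfg))
})

# DMR-calling scenario: 1-Mb single chromosome, 2 x 3 replicates, depth 20
dmr_scenario_config <- function(seed, planted = TRUE) {
  cfg <- sim_config(seed = seed, chrom_lengths = c(Chr1 = 1000000L),
                    plan = dup_plan(singleton = 150, tandem_pairs = 0,
                                    proximal_pairs = 0, dispersed_pairs = 0,
                                    seg2 = 0, seg3 = 0),
                    te_count = 50L)
  cfg$planted <- planted
  cfg
}

run_dmr_scenario <- function(seed, planted = TRUE) {
  cfg <- dmr_scenario_config(seed, planted)
  ann <- simulate_annotation(cfg)
  if (planted)
    cfg$dmrs <- plant_dmrs(ann, n = 200, width = 400, delta = 0.6,
                           context = "CG", seed = seed)
  ms <- simulate_methylome_set(ann, cfg)
  res <- call_dmrs(ms[1:3], ms[4:6], "CG")
  truth <- if (planted)
    GenomicRanges::GRanges(cfg$dmrs$chrom,
                           IRanges::IRanges(cfg$dmrs$start, cfg$dmrs$end))
  else GenomicRanges::GRanges()
  list(res = res, truth = truth)
}

dmr_recovery_stats <- function(seed) {
  run <- run_dmr_scenario(seed, planted = TRUE)
  called <- run$res$dmrs
  right_dir <- called[called$direction == "hypo"]  # B was shifted up
  c(sensitivity = mean(IRanges::overlapsAny(run$truth, right_dir)),
    fdr = if (length(called))
      mean(!IRanges::overlapsAny(called, run$truth)) else 0,
    n_called = length(called), n_tested = run$res$n_tested)
}

# hand-built CX-style call table: one row per site
make_calls <- function(chrom, pos, meth, unmeth, context = "CG",
                       strand = "+", tri = "CGT") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand,
                         count_meth = as.integer(meth),
                         count_unmeth = as.integer(unmeth),
                         context = context, tri = tri)
}
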