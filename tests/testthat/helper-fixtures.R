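# Shared fixtures. Small configurations keep unit tests fast; the full-scale
# study objects used by the acceptance tests are built once and cached.

small_truth <- function(seed = 1, ...) {
  args <- list(
    n_cells = 300, n_peaks = 400, n_genes = 60, n_tfs = 3, n_types = 6,
    modules_per_tf = 4, peaks_per_module = 2, genes_per_module = 2,
    n_decoy_motifs = 3, n_control_adts = 5, n_bound_extra = 40,
    n_decoy_sites = 15, mean_fragments = 600, seed = seed
  )
  generate_truth(do.call(sim_config, utils::modifyList(args, list(...))))
}

# QC bounds tuned to the small simulations (the defaults assume full depth)
small_pipeline_config <- function(...) {
  pipeline_config(peak_count_bounds = c(50, 1e5), rna_umi_bounds = c(20, 1e4),
                  metacell_size = 25, ...)
}

.phr_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.phr_cache[[name]])) .phr_cache[[name]] <- builder()
  .phr_cache[[name]]
}

default_truth <- function() cached("truth", function() {
  generate_truth(sim_config(seed = 1))
})

default_dataset <- function() cached("dataset", function() {
  simulate_counts(default_truth())
})

default_hits <- function() cached("hits", function() {
  scan_peaks(default_truth()$motifs, peak_sequences(default_truth()),
             cutoff = 400)
})

default_links <- function() cached("links", function() {
  run_linkage(default_dataset(), default_hits(), default_truth()$adt_map)
})
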