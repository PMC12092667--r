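# Small fixtures built in code at test time.

# a compact forward-strand site with two target Cs, for fast unit tests
toy_site <- function() {
  target_site("toy", beditscan:::.synth_amplicon(42L, 120L, 30L, 20L,
                                                 "forward", c(10L, 16L)),
              protospacer_start = 30, protospacer_len = 20,
              strand = "forward", target_c = c(10, 16))
}

# apply a category's substitutions to a site's amplicon
edited_read <- function(site, category) {
  beditscan:::category_sequence(site, category)
}

# a small two-replicate null count table with non-targeting rows
toy_screen <- function(n_genes = 20, n_nt = 50, seed = 5, effect = NULL,
                       dispersion = 0.1) {
  lib <- library_spec(n_genes, 5, n_nt, effect = effect)
  simulate_screen(lib, sim_config(depth = 200, dispersion = dispersion,
                                  seed = seed))
}
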