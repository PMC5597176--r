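## Hand-built landscapes for deterministic simulator tests.

## Wrap a template table into a synthetic_landscape so sample_fragments()
## can run on fully controlled inputs.
manual_landscape <- function(templates, chrom_lengths,
                             params = landscape_params()) {
  tpl <- copy(as.data.table(templates))
  defaults <- list(kind = "nucleosome", role = "manual",
                   gene_id = NA_character_, labile = FALSE,
                   f_light = 1, f_dark = 1)
  for (nm in names(defaults))
    if (!nm %in% names(tpl)) set(tpl, j = nm, value = defaults[[nm]])
  if (!"occ_high" %in% names(tpl)) set(tpl, j = "occ_high",
                                       value = tpl$occ_low)
  tpl[, start := as.integer(center - width %/% 2)]
  tpl[, end := as.integer(start + width)]
  setorder(tpl, chrom, center, start)
  tpl[, template_id := seq_len(.N)]
  cl <- cpsar:::chrom_length_vec(chrom_lengths)
  ann <- structure(list(chroms = data.table(chrom = names(cl),
                                            length = as.integer(cl)),
                        genes = data.table(), exons = data.table(),
                        cds = data.table()),
                   class = "genome_annotation")
  yields <- vapply(list(c("light", "low"), c("light", "high"),
                        c("dark", "low"), c("dark", "high")),
                   function(cd) sum(template_occupancy(tpl, cd[1], cd[2])),
                   numeric(1))
  structure(list(templates = tpl[], genes = data.table(), tfbs = NULL,
                 annotation = ann, params = params, seed = 0L,
                 expected_yield = max(mean(yields), 1e-9)),
            class = "synthetic_landscape")
}

## quiet digestion setting: no linkage, no jitter, no background
clean_digestion <- function(level = "low", p_link = 0, jitter = 0,
                            background = 0) {
  digestion_setting(level, p_link = p_link, boundary_jitter_sd = jitter,
                    background_rate = background)
}

## compact genome + landscape used by power-style simulations
small_experiment_landscape <- function(n_genes = 20L, seed = 1L,
                                       params = landscape_params()) {
  spec <- toy_genome_spec(chrom_lengths = c(chr1 = 80000L),
                          n_genes = n_genes, seed = seed)
  plant_landscape(build_toy_genome(spec), params, seed = seed + 1L)
}
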