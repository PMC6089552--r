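# Fixture builders used across test files.

# A full plate of wells with signals defined by a function of (row, col).
# Control wells sit in the first and last columns.
make_plate <- function(signal_fn, plate_format = 384, plate_id = "P01",
                       condition = "HIGH", screen_id = "S1") {
  dims <- if (plate_format == 384) c(16L, 24L) else c(8L, 12L)
  grid <- expand.grid(col = seq_len(dims[2]) - 1L, row = seq_len(dims[1]) - 1L)
  ctrl <- grid$col %in% c(0L, dims[2] - 1L)
  cmpd_i <- cumsum(!ctrl)
  data.frame(screen_id = screen_id, plate_id = plate_id,
             row = grid$row, col = grid$col,
             compound_id = ifelse(ctrl, "DMSO", sprintf("CID%04d", cmpd_i)),
             concentration = ifelse(ctrl, 0, 1),
             condition = condition,
             raw_signal = signal_fn(grid$row, grid$col),
             stringsAsFactors = FALSE)
}

# Minimal normalized-well rows from explicit log2 viabilities (one well per
# compound x concentration).
make_norm_wells <- function(log2_viability, compound_id, concentration = 1,
                            condition = "HIGH", screen_id = "S1") {
  n <- length(log2_viability)
  data.frame(screen_id = screen_id, plate_id = "P01",
             row = 0L, col = seq_len(n) - 1L,
             compound_id = compound_id,
             concentration = rep_len(concentration, n),
             condition = condition,
             raw_signal = 1e5,
             surface_fit = 1e5, corrected_signal = 1e5,
             viability = 2^log2_viability,
             log2_viability = log2_viability,
             floored = FALSE, stringsAsFactors = FALSE)
}

# Clean affinity record(s) for filter tests.
aff_record <- function(compound_id = "CID0001", gene = "G0001",
                       organism = "Homo sapiens", measure_type = "IC50",
                       measure_value = 500, measure_unit = "nM",
                       confidence = 5, reference = "PMID:1") {
  data.frame(compound_id = compound_id, gene = gene, organism = organism,
             measure_type = measure_type, measure_value = measure_value,
             measure_unit = measure_unit, confidence = confidence,
             reference = reference, stringsAsFactors = FALSE)
}

inter_record <- function(compound_id = "CID0001", gene = "G0001",
                         channel = "experimental", score = 0.9) {
  data.frame(compound_id = compound_id, gene = gene, channel = channel,
             score = score, stringsAsFactors = FALSE)
}
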