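Drop-in location for the externally distributed per-condition screen tables
used by the replication check in tests/testthat/test-acceptance.R. None of
these files ship with the package; place them here after downloading the
published supplementary datasets and converting to TSV.

Expected files and columns (tab-delimited, header row, '.' decimal):

  ratios_q.tsv            complex_id, condition, log2r_up, log2r_down,
                          q_up, q_down
                          -- one row per strain per condition from the
                          selective (+MTX) screen
  excluded_minus_mtx.tsv  complex_id, condition
                          -- strains with a selection-independent growth
                          change in that condition
  network_edges.tsv       protein_a, protein_b, complex_id, up_tag, down_tag
                          -- the measured interaction network, one row per
                          barcoded strain

With these present, the replication test recomputes the dual-tag calls,
exclusion propagation, per-complex dynamic frequencies, hub set and
concerted-hub set from the raw columns and compares the resulting counts
with the published ones.
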