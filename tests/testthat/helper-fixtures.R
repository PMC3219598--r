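# Shared expensive objects, built once per test run.
the_library <- element_library()
the_model <- nf1_gene_model()
the_fixtures <- build_fixture_set(library = the_library, model = the_model)

# full reproduction pipeline, reused by several files
the_reproduction <- reproduce_insertion_tables(the_fixtures)

# a tiny deterministic gene model: two exons of 100 nt around a 50-nt intron,
# no padding, for hand-checkable coordinate arithmetic
toy_model <- gene_model(
  tibble::tibble(index = 1:2, legacy_label = c("1", "2"),
                 c_start = c(1L, 101L), c_end = c(100L, 200L),
                 intron_after = c(50L, 0L)))
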