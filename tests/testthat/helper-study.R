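# Shared synthetic study at the default configuration (built lazily and
# cached so several test files can reuse it without regenerating).

default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(synthetic_config(), seed = 1L)
    }
    cache
  }
})

default_fig2_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- default_study()
      cache <<- run_fig2_analysis(st$genome, st$genes, st$domains,
                                  st$methylome)
    }
    cache
  }
})
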