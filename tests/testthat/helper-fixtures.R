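# Shared small fixtures, built in code at load time.

BIN_LEVELS_TEST <- enztriage:::BIN_LEVELS

# tiny reference set: three related proteins
tiny_refs <- function() {
  reference_set(c(rA = "MKTAYIAKQR", rB = "MKTAYIAKQK", rC = "MKTPYIAKQR"),
                length_mean = 10, length_sd = 0.5)
}

# a small triage fixture shared by pipeline-scale tests (cached per session)
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_triage_fixture(
        seed = 421L,
        bin_targets = c("40-50" = 7L, "50-60" = 7L, "60-70" = 7L,
                        "70-80" = 7L, "80-90" = 7L, "90-100" = 4L),
        n_active_site_fail = 4L, n_cluster_members = 12L,
        n_bad_start = 6L, n_bad_length = 6L, n_low_plddt = 6L,
        n_unrelated = 5L)
    }
    cache
  }
})

small_plan <- function() {
  selection_plan(quotas = c("80-90" = 4, "70-80" = 4, "60-70" = 3,
                            "50-60" = 2, "40-50" = 1))
}
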