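# Shared cached fixtures: generated once per test run, reused across files.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# one small CBD slide + truth (the workhorse fixture)
small_slide <- function() cached("small_slide", {
  generate_slide(synthetic_spec("CBD", slide_size = c(640L, 640L)), seed = 3L)
})

small_slide_ad <- function() cached("small_slide_ad", {
  generate_slide(synthetic_spec("AD", slide_size = c(640L, 640L)), seed = 4L)
})

# region benchmark (6 slides, trained test-preset FCN) - shared with
# acceptance tests; only the small fields are kept in the cache
region_bench <- function() cached("region_bench", {
  b <- benchmark_region(seed = 1L)
  b$cohort <- NULL
  gc(FALSE)
  b
})

# aggregate benchmark (6 slides, trained test-preset UNet); keeps only the
# two held-out slides needed by the IoU / feature-correlation criteria
aggregate_bench <- function() cached("aggregate_bench", {
  b <- benchmark_aggregate(seed = 1L)
  b$holdout <- b$cohort[5:6]
  b$cohort <- NULL
  gc(FALSE)
  b
})
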