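# Expensive fixture fits computed once per test session.
.fit_cache <- new.env(parent = emptyenv())

argylia_bayareaj_fit <- function() {
  if (is.null(.fit_cache$bayj)) {
    fx <- argylia_fixtures()
    .fit_cache$bayj <- fit_biogeo(fx$tree, fx$ranges, "BAYAREALIKE+J",
                                  fx$epochs)
  }
  .fit_cache$bayj
}

argylia_fx <- function() {
  if (is.null(.fit_cache$fx)) .fit_cache$fx <- argylia_fixtures()
  .fit_cache$fx
}
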