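# Builders used across test files. Fixtures are generated in code; nothing
# is read from disk except in the io tests' temp directories.

# complete strict instance with uniform-random rankings and random strict
# expert ranks
random_strict_instance <- function(p, n, m) {
  ids <- sprintf("E%d", seq_len(p))
  attrs <- sprintf("j%d", seq_len(n))
  alts <- sprintf("A%d", seq_len(m))
  opa_instance(
    ids, attrs, alts,
    setNames(lapply(ids, function(e) as.list(sample(attrs))), ids),
    setNames(lapply(ids, function(e)
      setNames(lapply(attrs, function(a) as.list(sample(alts))), attrs)),
      ids),
    expert_ranks = setNames(sample.int(p), ids))
}

# one expert, one attribute, strict order over m alternatives
micro_instance <- function(m) {
  alts <- sprintf("A%d", seq_len(m))
  opa_instance("E1", "j1", alts,
               list(E1 = list("j1")),
               list(E1 = list(j1 = as.list(alts))))
}

harmonic <- function(k) sum(1 / seq_len(k))
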