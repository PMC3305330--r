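# Shared fixtures: the worked MscL configuration and small helper builders.

mscl_channel <- function() channel_geometry(2.4, 3.5)

# uniform 1 nm crowders covering half the membrane: c = 0.5/pi nm^-2
mscl_mixture <- function() uniform_mixture(1, area_fraction = 0.5)

# write a TM-helix TSV (with a comment line) and return its path
write_tm_tsv <- function(n, abundance, dir = tempdir()) {
  path <- tempfile("tm_", tmpdir = dir, fileext = ".tsv")
  writeLines(c("# test table",
               "n_tm_helices\tabundance",
               sprintf("%d\t%g", as.integer(n), abundance)),
             path)
  path
}
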