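Placeholder for the study's published supplementary data, which are
third-party files not redistributed with this package:

  S2_procrustes_coords.csv  -- specimen id, taxon, tooth, side, then
                               Procrustes coordinates x1,y1,...,xp,yp
                               (the layout written by coords_table())
  S3_genome_phylogeny.nwk   -- rooted 10-taxon molecular phylogeny with
                               branch lengths, tips labelled by taxon code

Drop the files here (and reinstall) to enable the reproduction checks in
tests/testthat/test-acceptance.R.
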