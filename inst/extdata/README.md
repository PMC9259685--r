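# Bundled data files

## `gba_hg38_model.json`

A region model for the human GBA/GBAP1 locus (hg38) intended as a worked
example of the model format and for real-coordinate smoke tests. Only the
following coordinates are literature-anchored:

- unique CN-calling region chr1:155,220,429-155,230,539 (1-based);
- homopolymer runs chr1:155,239,990-155,239,995 and 155,239,657-155,239,661;
- the named variant positions p.L483P (g.155235252 A>G), p.A495P
  (g.155235216 C>G), p.D448H (g.155235727 C>G), c.1263del55
  (g.155235752_155235806del), p.N409S (g.155235843 T>G), p.E365K
  (g.155236376 C>T), p.T408M (g.155236246 G>A), c.84dupG (g.155240661dup);
- the long-read amplicon span chr1:155,232,524-155,241,392.

Everything else — the pseudogene interval, the coding interval, the
background differentiating-site positions and all site alleles not fixed by
the variants above — is a synthetic placeholder: the full 82-site
differentiating-site list is not reproduced here, so the model ships with
evenly spaced stand-in sites so that the loader, validator and exporters
can be exercised against a file with realistic shape. Three phasing sites
are flagged `reliable = false`, standing in for the sites whose hg38
pseudogene reference bases erroneously show the gene allele. Do not use
this file to call real samples; the test suite uses simulator-generated
models whose truth is known.

## `gba_cohort_counts.tsv`

Published per-cohort carrier counts for GBA coding variants (1kGP, PD and
LBD case/control cohorts): cohort size `N`, p.N409S carriers, severe-variant
carriers, total carriers, and total carriers excluding p.N409S. Input for
the cohort-statistics module (carrier-exclusion odds ratios, prevalences).

## `gba_cng_cooccurrence.tsv`

Counts of samples carrying a GBAP1-like coding variant among CNG carriers
(7/146) versus non-carriers (71/10,407), for the co-occurrence proportions.
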