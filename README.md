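# ppiref

Evidence-scored protein–protein interaction (PPI) reference networks for
the mouse, built from PSI-MITAB records.

Experimental mouse PPIs arrive from many molecular-interaction providers
with provider-specific identifiers, heterogeneous detection techniques and
wildly unequal supporting evidence. `ppiref` turns such records into one
scored reference network and gives bench and computational biologists the
query layer around it: context-specific subnetworks (tissue, GO/MeSH term,
interaction type, confidence), screen annotation against the reference,
and shortest-path directionality inference from receptors to transcription
factors.

## The confidence score

Every unordered protein pair gets an evidence bundle (studies, detection
techniques, interolog species) and a score

```
S = w_s·s_s + w_o·s_o + w_t·s_t,          w_s + w_o + w_t = 1
s_i(n) = 2 / (1 + exp(−α_i·n)) − 1  =  tanh(α_i·n / 2)  ∈ [0, 1)
```

where *n* is the number of supporting studies for `s_s` (α = 1, weight
0.6), the number of non-mouse species whose homologs also interact for
`s_o` (α = 1.5, weight 0.1), and the summed 0–10 reliability of the
distinct detection techniques for `s_t` (α = 0.5, weight 0.3): NMR and
light scattering count 10, two-hybrid and co-immunoprecipitation 5,
microscopy- and RNAi-based assays 1. Named confidence levels are score
quartiles; the published presets are medium = 0.53 (median) and
high = 0.60 (upper quartile), shipped as `confidence_presets()`.

## Worked example: the Hippo cascade

The packaged fixture contains the core Hippo signaling proteins (Stk4,
Sav1, Lats2, Yap1, Wwtr1, Tead4) with synthetic evidence and a
two-context expression matrix.

```r
library(ppiref)
dir <- file.path(tempdir(), "hippo")
hippo_fixture(dir)
ref <- build_reference(dir)    # parse -> filter -> map -> aggregate -> score
summary(ref$network)
#> PPI reference network
#>   proteins:      6
#>   interactions:  7
#>   confidence levels (quartiles): medium 0.90, high 0.90

protein_query(ref$network, "Lats2")[, c("partner_symbol", "score")]
#>   partner_symbol     score
#> 1           Yap1 0.9025881
#> 2           Stk4 0.9025881
#> 3           Sav1 0.9025881
#> 4          Wwtr1 0.9025881
```

Each score of 0.90 reflects three supporting studies (`s_s = tanh(1.5)`),
one interolog species (`s_o = tanh(0.75)`) and two techniques summing to
reliability 10 (`s_t = tanh(2.5)`). Restricting to the trophoblast
context and inferring directionality from Stk4 (source) to Tead4 (the
transcription-factor sink) recovers the kinase cascade:

```r
calls <- presence_calls(read_expression(file.path(dir, "expression.tsv")))
sub <- network_query(ref$network, proteins = c("Stk4", "Lats2", "Tead4"),
                     opts = query_options(tissue_filter = "trophoblast"),
                     calls = calls)
ov <- infer_direction(sub, sources = 58231, sinks = 21679)  # Stk4 -> Tead4
overlay_effects(ov, read_effects(file.path(dir, "effects.tsv")))
#>   entrez_a entrez_b orientation on_path     effect
#> 1    21679    22601      b_to_a    TRUE activation    # Yap1 -> Tead4
#> 2    21679    97064      b_to_a    TRUE       <NA>    # Wwtr1 -> Tead4
#> 3    22601    50523      b_to_a    TRUE inhibition    # Lats2 -> Yap1
#> 4    50523    58231      b_to_a    TRUE activation    # Stk4 -> Lats2
#> 5    50523    64010  undirected   FALSE       <NA>
#> 6    50523    97064      a_to_b    TRUE inhibition    # Lats2 -> Wwtr1
#> 7    58231    64010  undirected   FALSE       <NA>
```

Every edge on a shortest Stk4→Tead4 path is oriented downstream and
carries its curated activation/inhibition label; the two Sav1 scaffold
edges sit off the shortest paths and stay undirected. Switching the
tissue filter to `"stem cell"` drops the Yap1–Tead4 edge (Tead4 is below
the 1-TPM presence threshold there), mirroring the biology in which
cytoplasm-retained Yap1 cannot activate Tead4.

Queried pairs absent from the network are reported with the pseudo-score
−1, both in `network_query()` (explicit `A:B` pairs) and in
`screen_annotate()`, which appends one score column to an uploaded list
of candidate pairs.

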