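# Data dictionary

Formats written by `write_forest()` / the pipeline `synth` stage and
read by `read_forest()`.

## trees.csv — one row per stem

| column            | type    | units | meaning                                                        |
|-------------------|---------|-------|----------------------------------------------------------------|
| tree_id           | string  |       | unique stem identifier                                         |
| plot_id           | string  |       | plot the stem grows in                                         |
| species_id        | string  |       | species; matches phylogeny tip labels and traits.csv rows      |
| family_id         | string  |       | family; species are nested in families                         |
| subplot           | integer |       | 1-9 position on the 3x3 grid of 10 m subplots; 5 = centre      |
| x, y              | numeric | m     | stem coordinates within the 30 m plot                          |
| dbh               | numeric | cm    | diameter at breast height; NA when measured at the base only   |
| dbh_true          | numeric | cm    | latent generative DBH (synthetic data only, for validation)    |
| measured_at_base  | logical |       | TRUE if only a base-of-stem diameter was taken                 |
| basal_measure     | numeric | cm    | base-of-stem diameter (flagged stems + calibration subset)     |
| broken            | 0/1     |       | stem snapped in the storm                                      |
| dead              | 0/1     |       | stem died (only broken stems can die in the generator)         |
| height_to_break   | numeric | m     | height of the break point; present iff broken                  |
| p_break           | numeric |       | latent generative breakage probability (synthetic data only)   |

Sampling design: centre-subplot stems have `dbh >= 3` cm, stems in the
eight outer subplots `dbh >= 10` cm.

## plots.csv — one row per plot

| column            | type    | units      | meaning                                   |
|-------------------|---------|------------|-------------------------------------------|
| plot_id           | string  |            | plot identifier                           |
| elevation         | numeric | m a.s.l.   | covariate entering all mixed models       |
| stand_age         | numeric | years      | successional age                          |
| richness          | integer | species    | woody species count                       |
| cover_upper/lower/shrub | numeric | %    | cover of the three vegetation layers      |
| cover_total       | numeric | %          | combined cover                            |
| stem_density      | numeric | stems/ha   | stand structure descriptor                |
| rarefied_richness | numeric |            | diversity descriptor                      |
| rao_q             | numeric |            | Rao's quadratic entropy (functional)      |
| phylo_diversity   | numeric |            | phylogenetic diversity descriptor         |

Structure and diversity descriptors are reduced to `stand_axis_1/2` by
Gower + PCoA inside the attribution stage.

## traits.csv — one row per species

Columns: `species_id`, then the seven trait axes `wood_xylem_1`,
`wood_xylem_2`, `wood_mech_1`, `wood_mech_2`, `leaf_1`, `leaf_2`,
`wood_density` (dimensionless ordination-scale scores; empty cells are
missing values). The wood-mechanics axes are excluded from CWM/FDis by
default because of their high missingness.

## phylogeny.nwk

Newick 1.0, ultrametric, branch lengths required, tips = `species_id`.

## synth_config.json

The full generator configuration (see `?synth_config`), including the
master seed, written alongside the data for reproducibility.
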