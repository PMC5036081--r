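# Shipped data files

* `musm2538_measurements.csv`, `musm2548_measurements.csv` — published
  measurement tables (mm) of the holotype skulls of *Chavinziphius
  maxillocristatus* (MUSM 2538) and *Chimuziphius coloradensis* (MUSM 2548).
  `flag` column: `*` estimated by doubling a hemi-measurement, `+` preserved
  (minimum) distance.
* `rostrum_comparison.csv` — published comparative rostrum/mandible
  measurements (mm) for MUSM 1609, *Messapicetus gregarius* (MUSM 1037,
  MUSM 1038) and *Ninoziphius platyrostris* (MNHN SAS941); the B/A, C/A and
  D/A ratios of the source table are recomputed by the package, not stored.
* `ziphiidae_node_calibrations.tsv` — published node age constraints (Ma)
  for the major beaked-whale clades, with the clade membership used to
  resolve each node.
* `ziphiidae_tip_ranges.tsv` — published stratigraphic ranges (Ma) of the
  fossil species plus extant taxa (youngest = 0). Ranges resolved from
  broad verbal ages (e.g. "Neogene", "middle Miocene-Pliocene") via the
  package epoch table are flagged `low_confidence`.
* `ziphiidae_areas.tsv` — editable mapping of each taxon to the four
  distribution areas used for biogeographic mapping (A southeastern
  Pacific + North Atlantic + Mediterranean; B southern oceans;
  C cosmopolitan; D antitropical).
* `ziphiidae_standin_tree.nwk` — SYNTHETIC STAND-IN topology. The study's
  selected cladogram is not published in machine-readable form; this tree
  was assembled from the clades named in the text (stem position of
  Chavinziphius and Ninoziphius; Chimuziphius+Notoziphius basal in the
  Messapicetus clade; Messapicetus then Ziphirostrum next; Aporotus
  monophyletic; Choneziphius/Globicetus/Imocetus/Tusciziphius most derived
  in the MC; Tasmacetus then Nazcacetus basal in the crown; Berardiinae;
  Nenga sister to hyperoodontines+Pterocetus+Xhosacetus; Ziphius+
  Izikoziphius). Where the text is silent the resolution is arbitrary.
  It is a demonstration input for the calibration and mapping modules,
  not a result of this package.
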