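# Synthetic example: a fast grower ("Pp") and a slow grower ("Pv") whose
# outcome switches from slow- to fast-grower dominance with increasing
# dilution, passing through bistability.  Rates in 1/day; K in OD units.
unit: per_day
species:
  - name: Pp
    r: 24.0
    K: 1.2
  - name: Pv
    r: 11.5
    K: 1.1
alpha:
  - [1.0, 1.9]
  - [0.8, 1.0]
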