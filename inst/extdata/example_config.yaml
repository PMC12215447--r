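# Example run configuration for fjordnem. With input.bottles: simulate the
# pipeline runs on the built-in synthetic scenario; point it at a CSV/TSV
# bottle table for real data.
seed: 1
output_dir: fjordnem_out
input:
  bottles: simulate
  unit: umol_per_kg
  reference_density: 1000
water_masses:
  - {name: AW,  tmin: 3.0, smin: 34.9, priority: 1}
  - {name: TAW, tmin: 1.0, tmax: 3.0, smin: 34.7, priority: 2}
  - {name: ArW, tmin: -1.5, tmax: 1.0, smin: 34.3, smax: 34.8, priority: 3}
  - {name: IW,  tmin: 1.0, smin: 34.0, smax: 34.7, priority: 4}
  - {name: SW,  tmin: 1.0, smax: 34.0, priority: 5}
endmembers:
  nitrate_nitrite: 2.0
  ammonium: 1.44
  phosphate: 0.064
  silicic_acid: 9.77
  dic: regression
analysis:
  tracers: [nitrate_nitrite, dic]
  pairs: [AWs_vs_IW, AWs_vs_SW, AWs_vs_AWf]
  depth_max: 100
  alpha: 0.05
nem:
  ft_days: 13
  density: 1000
  area_km2: 231.5
  exclude: []
budget:
  area_km2: 231.5
  river_conc_uM: 2.0
  din_uM: 5.0
  constants:
    - {name: denitrification to atmosphere, category: internal_transformation,
       value: -3.0, season: summer, provenance: literature}
    - {name: bird consumption, category: biological, value: -0.13,
       season: summer, provenance: literature}
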