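country: new_zealand
arms:
- TLL
- HSR
- NIP
baseline_days: 7
intervention_days: 28
run_in_min_items: 15
run_in_grace_days: 7
strat_factors:
  ethnicity:
  - maori
  - pacific
  - other
  interest_healthy_eating:
  - low
  - high
block_sizes:
- 3
- 6
recruitment_days: 180
screening: default
schemes:
  DIG:
    energy_kj: 8700.0
    fat_g: 70.0
    satfat_g: 24.0
    sugars_g: 90.0
    sodium_mg: 2300.0
  TLL:
    food:
      nutrient:
      - fat
      - satfat
      - sugars
      - sodium
      low:
      - 3.0
      - 1.5
      - 5.0
      - 120.0
      high:
      - 17.5
      - 5.0
      - 22.5
      - 600.0
    beverage:
      nutrient:
      - fat
      - satfat
      - sugars
      - sodium
      low:
      - 1.5
      - 0.75
      - 2.5
      - 60.0
      high:
      - 8.75
      - 2.5
      - 11.25
      - 300.0
  HSR:
    baseline_food:
      energy:
        threshold:
        - 335.0
        - 670.0
        - 1005.0
        - 1340.0
        - 1675.0
        - 2010.0
        - 2345.0
        - 2680.0
        - 3015.0
        - 3350.0
        points:
        - 1
        - 2
        - 3
        - 4
        - 5
        - 6
        - 7
        - 8
        - 9
        - 10
      satfat:
        threshold:
        - 1.0
        - 2.0
        - 3.0
        - 4.0
        - 5.0
        - 6.0
        - 7.0
        - 8.0
        - 9.0
        - 10.0
        points:
        - 1
        - 2
        - 3
        - 4
        - 5
        - 6
        - 7
        - 8
        - 9
        - 10
      sugars:
        threshold:
        - 5.0
        - 9.0
        - 13.5
        - 18.0
        - 22.5
        - 27.0
        - 31.0
        - 36.0
        - 40.0
        - 45.0
        points:
        - 1
        - 2
        - 3
        - 4
        - 5
        - 6
        - 7
        - 8
        - 9
        - 10
      sodium:
        threshold:
        - 90.0
        - 180.0
        - 270.0
        - 360.0
        - 450.0
        - 540.0
        - 630.0
        - 720.0
        - 810.0
        - 900.0
        points:
        - 1
        - 2
        - 3
        - 4
        - 5
        - 6
        - 7
        - 8
        - 9
        - 10
    baseline_beverage:
      energy:
        threshold:
        - 140.0
        - 280.0
        - 420.0
        - 560.0
        - 700.0
        - 840.0
        - 980.0
        - 1120.0
        - 1260.0
        - 1400.0
        points:
        - 1
        - 2
        - 3
        - 4
        - 5
        - 6
        - 7
        - 8
        - 9
        - 10
      satfat:
        threshold:
        - 1.0
        - 2.0
        - 3.0
        - 4.0
        - 5.0
        - 6.0
        - 7.0
        - 8.0
        - 9.0
        - 10.0
        points:
        - 1
        - 2
        - 3
        - 4
        - 5
        - 6
        - 7
        - 8
        - 9
        - 10
      sugars:
        threshold:
        - 5.0
        - 9.0
        - 13.5
        - 18.0
        - 22.5
        - 27.0
        - 31.0
        - 36.0
        - 40.0
        - 45.0
        points:
        - 1
        - 2
        - 3
        - 4
        - 5
        - 6
        - 7
        - 8
        - 9
        - 10
      sodium:
        threshold:
        - 90.0
        - 180.0
        - 270.0
        - 360.0
        - 450.0
        - 540.0
        - 630.0
        - 720.0
        - 810.0
        - 900.0
        points:
        - 1
        - 2
        - 3
        - 4
        - 5
        - 6
        - 7
        - 8
        - 9
        - 10
    modifying:
      fvnl:
        threshold:
        - 40.0
        - 60.0
        - 67.0
        - 80.0
        points:
        - 1
        - 2
        - 5
        - 8
      protein:
        threshold:
        - 1.6
        - 3.2
        - 4.8
        - 6.4
        - 8.0
        - 9.6
        - 11.6
        - 13.9
        - 16.7
        - 20.0
        points:
        - 1
        - 2
        - 3
        - 4
        - 5
        - 6
        - 7
        - 8
        - 9
        - 10
      fibre:
        threshold:
        - 0.9
        - 1.9
        - 2.8
        - 3.7
        - 4.7
        - 5.4
        - 6.3
        - 7.3
        - 8.4
        - 9.7
        points:
        - 1
        - 2
        - 3
        - 4
        - 5
        - 6
        - 7
        - 8
        - 9
        - 10
    star_map_food:
      max_score:
      - -6.0
      - -3.0
      - 0.0
      - 3.0
      - 6.0
      - 9.0
      - 12.0
      - 15.0
      - 18.0
      - .inf
      stars:
      - 5.0
      - 4.5
      - 4.0
      - 3.5
      - 3.0
      - 2.5
      - 2.0
      - 1.5
      - 1.0
      - 0.5
    star_map_beverage:
      max_score:
      - -6.0
      - -3.0
      - 0.0
      - 3.0
      - 6.0
      - 9.0
      - 12.0
      - 15.0
      - 18.0
      - .inf
      stars:
      - 5.0
      - 4.5
      - 4.0
      - 3.5
      - 3.0
      - 2.5
      - 2.0
      - 1.5
      - 1.0
      - 0.5
  WARNING:
    thresholds:
      nutrient:
      - energy
      - satfat
      - sugars
      - sodium
      threshold:
      - 1700.0
      - 5.0
      - 22.5
      - 600.0
      text:
      - HIGH_IN_ENERGY
      - HIGH_IN_SAT_FAT
      - HIGH_IN_SUGARS
      - HIGH_IN_SODIUM
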