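calendar:
  transplant_date: '2024-03-14'
  stages:
    vegetative:
      end_dat: 50
    reproductive:
      end_dat: 109
    harvest:
      end_dat: 190
thresholds:
  vegetative:
    day:
      T:
        optimal:
        - 20.0
        - 28.0
        critical_below: 18.0
        critical_above: 34.0
      RH:
        optimal:
        - 55.0
        - 75.0
        critical_below: 50.0
        critical_above: 85.0
      VPD:
        optimal:
        - 0.5
        - 1.1
        critical_below: 0.4
        critical_above: 2.0
    night:
      T:
        optimal:
        - 15.0
        - 19.0
        critical_below: 12.0
        critical_above: 20.0
      RH:
        optimal:
        - 50.0
        - 75.0
        critical_below: 45.0
        critical_above: 80.0
      VPD:
        optimal:
        - 0.5
        - 0.9
        critical_below: 0.3
        critical_above: 1.5
  reproductive:
    day:
      T:
        optimal:
        - 19.0
        - 26.0
        critical_below: 17.0
        critical_above: 34.0
      RH:
        optimal:
        - 50.0
        - 80.0
        critical_below: 45.0
        critical_above: 89.0
      VPD:
        optimal:
        - 0.5
        - 1.2
        critical_below: 0.4
        critical_above: 2.0
    night:
      T:
        optimal:
        - 15.0
        - 19.0
        critical_below: 13.0
        critical_above: 20.0
      RH:
        optimal:
        - 50.0
        - 75.0
        critical_below: 45.0
        critical_above: 85.0
      VPD:
        optimal:
        - 0.5
        - 0.9
        critical_below: 0.3
        critical_above: 1.5
  harvest:
    day:
      T:
        optimal:
        - 19.0
        - 24.0
        critical_below: 17.0
        critical_above: 34.0
      RH:
        optimal:
        - 50.0
        - 80.0
        critical_below: 45.0
        critical_above: 89.0
      VPD:
        optimal:
        - 0.5
        - 1.2
        critical_below: 0.4
        critical_above: 2.0
    night:
      T:
        optimal:
        - 15.0
        - 19.0
        critical_below: 13.0
        critical_above: 20.0
      RH:
        optimal:
        - 50.0
        - 75.0
        critical_below: 45.0
        critical_above: 85.0
      VPD:
        optimal:
        - 0.5
        - 0.9
        critical_below: 0.3
        critical_above: 1.5
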