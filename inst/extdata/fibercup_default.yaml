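bundle_diameter: 120.0
fiber_diameter: 1.5
fiber_gap: 1.5
plate_diameter: 1000.0
samples_per_fiber: 42
bundles:
  bundle_1:
    x:
    - -190.0
    - -329.0896534
    - -380.0
    - -329.0896534
    - -190.0
    'y':
    - 329.0896534
    - 190.0
    - 4.6536578e-14
    - -1.9e+02
    - -3.2908965e+02
    z:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  bundle_2:
    x:
    - 180.0
    - 280.0
    - 380.0
    'y':
    - -430.0
    - -15.0
    - 400.0
    z:
    - 0.0
    - 0.0
    - 0.0
  bundle_3:
    x:
    - -480.0
    - 0.0
    - 480.0
    'y':
    - 0.0
    - 0.0
    - 0.0
    z:
    - 0.0
    - 0.0
    - 0.0
  bundle_4:
    x:
    - -440.0
    - -360.0
    - -290.0
    - -262.0
    - -260.0
    - -260.0
    - -260.0
    'y':
    - -350.0
    - -280.0
    - -190.0
    - -110.0
    - 0.0
    - 200.0
    - 380.0
    z:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  bundle_5:
    x:
    - -80.0
    - -160.0
    - -230.0
    - -258.0
    - -260.0
    - -260.0
    - -260.0
    'y':
    - -440.0
    - -350.0
    - -220.0
    - -110.0
    - 0.0
    - 200.0
    - 380.0
    z:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  bundle_6:
    x:
    - -260.0
    - -260.0
    - -260.0
    - -260.0
    - -260.0
    - -260.0
    'y':
    - -470.0
    - -300.0
    - -150.0
    - 0.0
    - 200.0
    - 380.0
    z:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
  bundle_7:
    x:
    - 60.0
    - 120.0
    - 210.0
    - 330.0
    - 430.0
    'y':
    - 430.0
    - 330.0
    - 260.0
    - 230.0
    - 150.0
    z:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
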