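version: 1
instruments:
  BHS4:
    full_name: Beck Hopelessness Scale, 4-item short form
    n_items: 4
    value_range: [0, 3]
    value_labels:
      0: not typical
      1: rarely typical
      2: typical
      3: very typical
    total_range: [0, 12]
    cutoffs:
      suicide_risk_min: 6
      very_high_risk_min: 9
    items:
      - My future seems dark to me
      - Things just won't work out the way I want them to
      - There's no use in really trying to get something I want because I probably won't get it
      - I feel that the future is hopeless and that things cannot improve
  BDI9:
    full_name: Beck Depression Inventory, 9-item short form (Hungarian)
    n_items: 9
    value_range: [1, 4]
    value_labels:
      1: not typical
      2: rarely typical
      3: typical
      4: very typical
    total_range: [9, 36]
    severity_bands:
      NO_DEPRESSION: [9, 13]
      MILD: [14, 18]
      MODERATE: [19, 24]
      SEVERE: [25, 36]
    # Items 4 and 6 are worded identically in the published Hungarian short
    # form (the nine constructs include both somatic preoccupation and work
    # difficulty); the wording is carried verbatim as a documented erratum.
    # Only totals enter the scoring, so it has no numerical effect.
    items:
      - I have lost all of my interest in other people
      - I can't make decisions at all anymore
      - I wake up several hours earlier than I used to and cannot get back to sleep
      - I am so worried about my physical problems that I cannot think of anything else
      - I am too tired to do anything
      - I am so worried about my physical problems that I cannot think of anything else
      - I feel the future is hopeless and that things cannot improve
      - I am dissatisfied or bored with everything
      - I feel guilty all of the time
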