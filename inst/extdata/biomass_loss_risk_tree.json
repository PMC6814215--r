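{
  "name": "biomass_loss_risk",
  "comment": "Default Biomass Loss Risk logic tree. Input-node thresholds are the frozen 'paper' profile; derived profiles may override them at load time.",
  "nodes": [
    {
      "name": "mc2_biomass_burned_high",
      "statement": "MC2 Biomass Burned is High",
      "kind": "input",
      "input_variable": "mc2_biomass_burned",
      "conversion": { "false": 0, "true": 110 }
    },
    {
      "name": "mc2_fire_frequency_high",
      "statement": "MC2 Fire Frequency is High",
      "kind": "input",
      "input_variable": "mc2_fire_frequency",
      "conversion": { "false": 0.0, "true": 1.0 }
    },
    {
      "name": "mc2_biomass_high",
      "statement": "MC2 Biomass is High",
      "kind": "input",
      "input_variable": "mc2_biomass",
      "conversion": { "false": 31572, "true": 73148 }
    },
    {
      "name": "mc2_live_biomass_high",
      "statement": "MC2 Live Biomass is High",
      "kind": "input",
      "input_variable": "mc2_live_biomass",
      "conversion": { "false": 5839, "true": 29387 }
    },
    {
      "name": "mc2_vegetation_stress",
      "statement": "MC2 Vegetation Stress is High",
      "kind": "input",
      "input_variable": "vegetation_departure",
      "conversion": { "false": 0, "true": 3 }
    },
    {
      "name": "hudiburg_biomass_high",
      "statement": "Hudiburg Biomass is High",
      "kind": "input",
      "input_variable": "hudiburg_biomass",
      "conversion": { "false": 4053, "true": 21844 }
    },
    {
      "name": "mc2_fire_threat",
      "statement": "MC2 Fire Threat is High",
      "kind": "union",
      "children": ["mc2_biomass_burned_high", "mc2_fire_frequency_high"]
    },
    {
      "name": "mc2_fire_loss_risk",
      "statement": "Risk of Biomass Loss to Fire is High",
      "kind": "and",
      "children": ["mc2_fire_threat", "mc2_biomass_high"]
    },
    {
      "name": "mc2_mortality_risk",
      "statement": "Risk of Biomass Loss to Mortality is High",
      "kind": "and",
      "children": ["mc2_vegetation_stress", "mc2_live_biomass_high"]
    },
    {
      "name": "mc2_biomass_loss_risk",
      "statement": "MC2 Risk of Biomass Loss is High",
      "kind": "or",
      "children": ["mc2_fire_loss_risk", "mc2_mortality_risk"]
    },
    {
      "name": "biomass_loss_risk",
      "statement": "Risk of Biomass Loss is High",
      "kind": "and",
      "children": ["mc2_biomass_loss_risk", "hudiburg_biomass_high"]
    }
  ]
}
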