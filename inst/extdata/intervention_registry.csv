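item_id,label,options
feel_fat,Feel fat,Exposure; imaginal exposure; mindfulness
fear_weight,Fear weight,Imaginal exposure
worth_weight,Worth weight,CBT-E cognitive techniques; mindfulness-based acceptance techniques
skip_meals_urge,Skip meals urge,CBT-E self-monitoring
food_rules_restrict,Food rules restrict,CBT-E behavioral experiments
restrict_food_urge,Restrict food urge,CBT-E self-monitoring
mirror_checking,Mirror checking,CBT-E cognitive strategies; mindfulness-based acceptance techniques
desire_live,Desire live,DBT skills (Accumulating Positive Emotions); Behavioral Activation
fear_death,Fear of death,Means safety; safety planning
reasons_die,Reasons to die,Reasons for living
passive_ideation_1,Passive ideation 1,DBT skills; Behavioral Activation
problem_solving,Problem solving,Safety planning; problem-solving therapy
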