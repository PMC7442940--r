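outcome,denominator,yes_older,n_older,yes_younger_equal,n_younger_equal,yes_younger,n_younger,yes_equal,n_equal
recall_correct,all,735,1055,157,248,104,155,53,93
very_motivated,all,406,1055,101,248,NA,NA,NA,NA
very_optimistic,all,229,1055,95,248,NA,NA,NA,NA
very_anxious,all,159,1055,8,248,NA,NA,NA,NA
very_worried,all,151,1055,9,248,NA,NA,NA,NA
spoke_family,all,466,1055,89,248,NA,NA,NA,NA
found_info,all,669,1055,118,248,NA,NA,NA,NA
told_others,all,397,1055,95,248,NA,NA,NA,NA
increased_activity,all,668,1055,141,248,NA,NA,NA,NA
lost_weight,all,537,1055,106,248,NA,NA,NA,NA
improved_diet,all,680,1055,141,248,NA,NA,NA,NA
reduced_smoking,smokers,19,39,0,0,NA,NA,NA,NA
reduced_stress,all,333,1055,79,248,NA,NA,NA,NA
limited_alcohol,all,332,1055,74,248,NA,NA,NA,NA
saw_gp,all,538,1055,83,248,NA,NA,NA,NA
heart_health_check,all,314,1055,48,248,NA,NA,NA,NA
bp_check,all,809,1055,167,248,NA,NA,NA,NA
cholesterol_test,all,619,1055,118,248,NA,NA,NA,NA
diabetes_test,all,587,1055,110,248,NA,NA,NA,NA
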