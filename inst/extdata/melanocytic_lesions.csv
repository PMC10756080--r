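lesion,group,histological_subtype,breslow_mm
IN1,nevus,intradermal,NA
IN2,nevus,intradermal,NA
IN3,nevus,intradermal,NA
IN4,nevus,intradermal,NA
IN5,nevus,intradermal,NA
IM1,melanoma,invasive,0.9
IM2,melanoma,invasive,1.4
IM3,melanoma,invasive,6.0
IM4,melanoma,invasive,2.5
IM5,melanoma,invasive,0.5
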