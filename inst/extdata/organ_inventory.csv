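organ,region
brain,head_and_neck
brainstem,head_and_neck
eye_globe_right,head_and_neck
eye_globe_left,head_and_neck
lens_right,head_and_neck
lens_left,head_and_neck
optic_nerve_right,head_and_neck
optic_nerve_left,head_and_neck
parotid_right,head_and_neck
parotid_left,head_and_neck
submandibular_right,head_and_neck
submandibular_left,head_and_neck
mandible,head_and_neck
heart,chest
lung_right,chest
lung_left,chest
spinal_cord,chest
esophagus,chest
breast_right,chest
breast_left,chest
liver,abdomen
spleen,abdomen
kidney_right,abdomen
kidney_left,abdomen
prostate,pelvis
seminal_vesicle,pelvis
bladder,pelvis
rectum,pelvis
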