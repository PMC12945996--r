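"pt","category","scope"
"Pulmonary embolism","venous_thromboembolic","narrow"
"Deep vein thrombosis","venous_thromboembolic","narrow"
"Portal vein thrombosis","venous_thromboembolic","narrow"
"Cerebral venous sinus thrombosis","venous_thromboembolic","narrow"
"Renal vein thrombosis","venous_thromboembolic","narrow"
"Cerebral venous thrombosis","venous_thromboembolic","narrow"
"Pulmonary thrombosis","venous_thromboembolic","narrow"
"Pulmonary infarction","venous_thromboembolic","narrow"
"Thrombophlebitis","venous_thromboembolic","narrow"
"Venous thrombosis","venous_thromboembolic","narrow"
"Mesenteric vein thrombosis","venous_thromboembolic","narrow"
"Venous thrombosis limb","venous_thromboembolic","narrow"
"Superficial vein thrombosis","venous_thromboembolic","narrow"
"Transverse sinus thrombosis","venous_thromboembolic","narrow"
"Pulmonary artery thrombosis","venous_thromboembolic","narrow"
"Superior sagittal sinus thrombosis","venous_thromboembolic","narrow"
"Splenic vein thrombosis","venous_thromboembolic","narrow"
"Embolism venous","venous_thromboembolic","narrow"
"Jugular vein thrombosis","venous_thromboembolic","narrow"
"Vena cava thrombosis","venous_thromboembolic","narrow"
"Subclavian vein thrombosis","venous_thromboembolic","narrow"
"Pelvic venous thrombosis","venous_thromboembolic","narrow"
"Retinal vein thrombosis","venous_thromboembolic","narrow"
"Acute myocardial infarction","arterial_thromboembolic","narrow"
"Acute coronary syndrome","arterial_thromboembolic","narrow"
"Arterial thrombosis","arterial_thromboembolic","narrow"
"Peripheral arterial occlusive disease","arterial_thromboembolic","narrow"
"Lacunar infarction","arterial_thromboembolic","narrow"
"Peripheral artery occlusion","arterial_thromboembolic","narrow"
"Embolism arterial","arterial_thromboembolic","narrow"
"Aortic thrombosis","arterial_thromboembolic","narrow"
"Renal artery thrombosis","arterial_thromboembolic","narrow"
"Hepatic artery thrombosis","arterial_thromboembolic","narrow"
"Transient ischaemic attack","arterial_thromboembolic","narrow"
"Ischaemic stroke","arterial_thromboembolic","narrow"
"Peripheral artery thrombosis","arterial_thromboembolic","narrow"
"Carotid artery thrombosis","arterial_thromboembolic","narrow"
"Cerebral artery thrombosis","arterial_thromboembolic","narrow"
"Retinal artery thrombosis","arterial_thromboembolic","narrow"
"Embolism","mixed_other_embolic","narrow"
"Renal embolism","mixed_other_embolic","narrow"
"Peripheral embolism","mixed_other_embolic","narrow"
"Postoperative thrombosis","mixed_other_embolic","narrow"
"Thrombotic thrombocytopenic purpura","mixed_other_embolic","narrow"
"Coronary artery bypass","mixed_other_embolic","narrow"
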