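高血压	C001	Disease
低血压	C002	Disease
糖尿病	C003	Disease
冠心病	C004	Disease
高血脂	C005	Disease
肾病	C006	Disease
心脏病	C007	Disease
脑梗塞	C008	Disease
降压药	C101	Drug
硝苯地平	C102	Drug
卡托普利	C103	Drug
氨氯地平	C104	Drug
缬沙坦	C105	Drug
倍他乐克	C106	Drug
利尿剂	C107	Drug
阿司匹林	C108	Drug
头晕	C201	Symptom
头痛	C202	Symptom
心慌	C203	Symptom
胸闷	C204	Symptom
耳鸣	C205	Symptom
乏力	C206	Symptom
恶心	C207	Symptom
心悸	C208	Symptom
失眠	C209	Symptom
出冷汗	C210	Symptom
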