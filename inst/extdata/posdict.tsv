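头晕	n
头痛	n
心慌	n
胸闷	n
耳鸣	n
乏力	n
恶心	n
心悸	n
失眠	n
出冷汗	n
高血压	n
低血压	n
糖尿病	n
冠心病	n
高血脂	n
肾病	n
心脏病	n
脑梗塞	n
降压药	n
硝苯地平	n
卡托普利	n
氨氯地平	n
缬沙坦	n
倍他乐克	n
利尿剂	n
阿司匹林	n
盐	n
肉	n
鸡蛋	n
水果	n
蔬菜	n
咖啡	n
浓茶	n
海鲜	n
心内科	n
内科	n
急诊	n
神经内科	n
血压	n
高压	n
医院	n
医生	n
科室	n
专家	n
病	n
原因	n
症状	n
检查	n
剂量	n
药	n
效果	n
费用	n
孩子	n
人群	n
年轻人	n
概率	n
发病率	n
风险	n
病人	n
病情	n
饮食	n
体检	n
血压计	n
副作用	n
禁忌	n
疗效	n
早餐	n
体重	n
医保	n
挂号	n
病情描述	n
帮助	n
跑步	v
游泳	v
爬山	v
健身	v
打球	v
吃	v
服用	v
得	v
得了	v
做	v
治	v
治疗	v
控制	v
监测	v
测量	v
注意	v
调整	v
调理	v
保养	v
管理	v
遗传	v
引起	v
增加	v
挂	v
就诊	v
看	v
买	v
报销	v
诊断	v
判断	v
确诊	v
查明	v
饮酒	v
熬夜	v
应酬	v
锻炼	v
伴有	v
发现	v
去	v
降血压	v
最近	x
总是	x
以往	x
最好	x
比较	x
合适	x
平时	x
日常	x
长期	x
经常	x
每天	x
网上	x
这种	x
情况	x
需要	x
应该	x
才能	x
可以	x
一直	x
一次	x
稳定	x
偏高	x
忽高忽低	x
服药	x
期间	x
容易	x
靠谱	x
准不准	x
有点	x
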