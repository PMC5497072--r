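一次
一直
专家
为什么
为啥
乏力
买
人群
什么
什么时候
以往
会不会
伴有
低血压
体检
体重
何时
保养
倍他乐克
偏高
做
健身
内科
冠心病
准不准
几
出冷汗
判断
利尿剂
剂量
副作用
医保
医生
医院
卡托普利
原因
去
发现
发病率
可不可以
可以
可否
吃
合适
吗
吧
呢
咋
咖啡
哪
哪个
哪些
哪儿
哪家
哪种
哪里
啥
增加
多久
多大
多少
多重
多长时间
多高
失眠
头晕
头痛
好不好
如何
孩子
容易
对不对
就诊
帮助
平时
年轻人
应该
应酬
引起
得
得了
心内科
心悸
心慌
心脏病
忽高忽低
怎么
怎么办
怎么回事
怎样
急诊
总是
恶心
情况
才能
打球
报销
挂
挂号
控制
效果
日常
早餐
是不是
是否
最好
最近
有没有
有点
服用
服药
期间
查明
检查
概率
每天
比较
氨氯地平
水果
治
治疗
注意
测量
浓茶
海鲜
游泳
熬夜
爬山
疗效
病
病人
病情
病情描述
症状
盐
监测
看
硝苯地平
确诊
神经内科
禁忌
科室
稳定
管理
糖尿病
经常
缬沙坦
网上
耳鸣
肉
肾病
胸闷
能不能
能否
脑梗塞
药
蔬菜
血压
血压计
行不行
要不要
诊断
该不该
调整
调理
费用
跑步
这种
遗传
锻炼
长期
阿司匹林
降压药
降血压
需要
靠谱
风险
饮酒
饮食
高压
高血压
高血脂
鸡蛋
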