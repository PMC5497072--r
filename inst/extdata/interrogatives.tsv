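什么
怎么
怎样
如何
为什么
为啥
哪
哪些
哪个
哪种
哪家
哪里
哪儿
几
多少
多久
多长时间
多大
多高
多重
吗
呢
吧
啥
咋
何时
什么时候
怎么办
怎么回事
是否
能否
可否
会不会
能不能
可不可以
要不要
该不该
好不好
行不行
有没有
是不是
对不对
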