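When confronted with topics that might be personally meaningful, the subject denies they are important and refuses to talk about them further.
The subject complains spontaneously about how others don’t really care, or have made his or her problems worse, even when there is clear evidence that others have tried to help.
At times when expressing an opinion or wish might be helpful, the subject fails to express himself adequately, instead finding indirect, even annoying ways to show his or her opposition to the influence of others, for example, being silent.
The subject recites a litany of issues and problems but does not appear to be engaged in solving them, but rather prefers to complain.
When others comment or inquire about the subject’s own feelings, actions, or intentions, the subject is very elusive or frankly denies the material, but the subject subsequently talks about similar feelings, actions, intentions, etc. in others.
Whenever talking about potentially distressing events or experiences, the subject strongly claims not to have any feelings about the topic, although this seems highly unlikely.
When telling an emotionally meaningful story, the subject states that he or she does not have specific feelings that one would expect, although the subject recognizes that he or she should feel something.
In talking about a meaningful, emotionally charged experience, the subject talks in a detached way, as if he or she is not in touch with the feelings that should surround it.
The subject avoids feelings of guilt or shame by justifying his actions or by referring to external reasons that impelled him to act.
At times the subject’s feelings merge with those of another person and the subject assumes the other’s feelings and needs are exactly the same as the subject’s own. He or she then tends to ‘put words in the other’s mouth.’
Whenever confronted about his or her own feelings or intentions, the subject avoids acknowledging them by giving a plausible explanation that covers up the real subjective reasons.
When angry toward someone significant, the subject takes anger out on himself instead of expressing it directly.
The subject expresses hatred toward someone or something and refuses to acknowledge anything that does not confirm the hatred.
When experiencing or confronted with a problem, the subject shames, humiliates, or blames someone else for the problem, ignoring his or her own role.
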